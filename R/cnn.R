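# Compact 2-D convolutional network used by both the beat and the rhythm
# classifier. Architecture: fixed average-pool on the input, one
# convolutional layer (im2col + BLAS matmul), ReLU, max-pool along the time
# axis, one hidden dense ReLU layer, softmax output. Trained with Adam on
# cross-entropy, optionally with weighted-with-replacement mini-batch
# sampling for class imbalance. Everything is deterministic given the seed.

# average-pool a H x W matrix by (pr, pc); trailing remainder cropped
avg_pool2 <- function(x, pr, pc) {
  h1 <- nrow(x) %/% pr; w1 <- ncol(x) %/% pc
  x <- x[seq_len(h1 * pr), seq_len(w1 * pc), drop = FALSE]
  # pool rows then columns via reshape tricks
  dim(x) <- c(pr, h1 * w1 * pc)
  x <- colMeans(x)
  dim(x) <- c(h1, pc, w1)
  colMeans(aperm(x, c(2, 1, 3)))       # -> h1 x w1
}

cnn_geometry <- function(input_dim, pool, kernel, stride, mp) {
  h1 <- input_dim[1] %/% pool[1]
  w1 <- input_dim[2] %/% pool[2]
  kh <- min(kernel[1], h1); kw <- min(kernel[2], w1)
  nh <- (h1 - kh) %/% stride[1] + 1L
  nw <- (w1 - kw) %/% stride[2] + 1L
  mp <- min(mp, nh)
  ngh <- nh %/% mp
  npos <- nh * nw
  # im2col linear indices into the pooled (h1 x w1) matrix, column-major;
  # position order: h fastest, then w
  base <- as.vector(outer(seq_len(kh), (seq_len(kw) - 1L) * h1, `+`))  # patch offsets
  origin <- as.vector(outer((seq_len(nh) - 1L) * stride[1],
                            (seq_len(nw) - 1L) * stride[2] * h1, `+`))
  idx <- outer(base, origin, `+`)                     # patch_len x npos
  # rows of the position axis kept by the max-pool (h cropped to mp*ngh),
  # ordered r-within-group fastest, then group, then w
  sel <- as.vector(outer(seq_len(mp * ngh), (seq_len(nw) - 1L) * nh, `+`))
  list(h1 = h1, w1 = w1, kh = kh, kw = kw, nh = nh, nw = nw, mp = mp,
       ngh = ngh, npos = npos, patch_len = kh * kw, idx = idx, sel = sel,
       g1 = ngh * nw, flat = ngh * nw * 0L)           # flat set after nf known
}

#' @keywords internal
cnn_init <- function(input_dim, n_classes, n_filters = 8L, kernel = c(11L, 0L),
                     stride = c(2L, 1L), pool = c(2L, 10L), mp = 2L,
                     hidden = 32L, seed = 1L) {
  if (kernel[2] <= 0) kernel[2] <- input_dim[2] %/% pool[2]  # full width
  geo <- cnn_geometry(input_dim, pool, kernel, stride, mp)
  flat <- geo$g1 * n_filters
  with_seed(seed, {
    sd_c <- sqrt(2 / geo$patch_len)
    sd_1 <- sqrt(2 / flat)
    sd_2 <- sqrt(2 / hidden)
    params <- list(
      Wc = matrix(stats::rnorm(geo$patch_len * n_filters, 0, sd_c),
                  geo$patch_len, n_filters),
      bc = numeric(n_filters),
      W1 = matrix(stats::rnorm(flat * hidden, 0, sd_1), flat, hidden),
      b1 = numeric(hidden),
      W2 = matrix(stats::rnorm(hidden * n_classes, 0, sd_2), hidden, n_classes),
      b2 = numeric(n_classes)
    )
    structure(list(input_dim = input_dim, n_classes = n_classes,
                   n_filters = n_filters, pool = pool, geo = geo,
                   hidden = hidden, params = params), class = "bsmecg_cnn")
  })
}

# pool + im2col one image -> patch_len x npos matrix
cnn_im2col <- function(model, img) {
  if (!all(dim(img) == model$input_dim)) {
    stop("image shape ", paste(dim(img), collapse = "x"),
         " does not match model input ", paste(model$input_dim, collapse = "x"))
  }
  p <- avg_pool2(img, model$pool[1], model$pool[2])
  matrix(p[model$geo$idx], nrow = model$geo$patch_len)
}

# stack im2col matrices of a list of images into one (n*npos) x patch matrix
cnn_prepare <- function(model, images) {
  mats <- lapply(images, function(im) t(cnn_im2col(model, im)))
  do.call(rbind, mats)                                 # (n*npos) x patch_len
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass on prepared rows for a set of samples; returns activations
cnn_forward <- function(model, Pbatch, B) {
  g <- model$geo; pm <- model$params
  nf <- model$n_filters
  Z1 <- Pbatch %*% pm$Wc
  Z1 <- sweep(Z1, 2, pm$bc, `+`)
  A1 <- pmax(Z1, 0)
  rows_sel <- rep((seq_len(B) - 1L) * g$npos, each = length(g$sel)) +
    rep(g$sel, B)
  A1s <- A1[rows_sel, , drop = FALSE]                  # (mp*g1*B) x nf
  G <- g$g1 * B
  arr <- array(A1s, dim = c(g$mp, G, nf))
  maxv <- arr[1, , , drop = TRUE]
  if (G == 1 || nf == 1) maxv <- matrix(maxv, G, nf)
  amax <- matrix(1L, G, nf)
  if (g$mp > 1) for (r in 2:g$mp) {
    layer <- matrix(arr[r, , ], G, nf)
    upd <- layer > maxv
    amax[upd] <- r
    maxv[upd] <- layer[upd]
  }
  arrH <- array(maxv, c(g$g1, B, nf))
  H <- matrix(aperm(arrH, c(2, 1, 3)), nrow = B)       # B x (g1*nf)
  Z2 <- sweep(H %*% pm$W1, 2, pm$b1, `+`)
  A2 <- pmax(Z2, 0)
  Z3 <- sweep(A2 %*% pm$W2, 2, pm$b2, `+`)
  list(Z1 = Z1, A1s = A1s, rows_sel = rows_sel, amax = amax, H = H,
       Z2 = Z2, A2 = A2, probs = softmax_rows(Z3))
}

# gradients of mean cross-entropy for one batch; Y is B x K one-hot
cnn_backward <- function(model, Pbatch, fw, Y) {
  g <- model$geo; pm <- model$params
  B <- nrow(Y); nf <- model$n_filters
  dZ3 <- (fw$probs - Y) / B
  gW2 <- crossprod(fw$A2, dZ3); gb2 <- colSums(dZ3)
  dZ2 <- (dZ3 %*% t(pm$W2)) * (fw$Z2 > 0)
  gW1 <- crossprod(fw$H, dZ2); gb1 <- colSums(dZ2)
  dH <- dZ2 %*% t(pm$W1)                               # B x (g1*nf)
  G <- g$g1 * B
  dMax <- matrix(aperm(array(dH, c(B, g$g1, nf)), c(2, 1, 3)), nrow = G)
  dA1s <- matrix(0, g$mp * G, nf)
  for (r in seq_len(g$mp)) {
    rows_r <- seq(r, by = g$mp, length.out = G)
    dA1s[rows_r, ] <- dMax * (fw$amax == r)
  }
  dZ1s <- dA1s * (fw$A1s > 0)
  Psel <- Pbatch[fw$rows_sel, , drop = FALSE]
  gWc <- crossprod(Psel, dZ1s); gbc <- colSums(dZ1s)
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' @keywords internal
cnn_train <- function(model, images, y, epochs = 30, learning_rate = 0.001,
                      batch_size = 16, seed = 1L, sample_weights = NULL) {
  n <- length(images)
  stopifnot(n == length(y), all(y >= 1), all(y <= model$n_classes))
  Pall <- cnn_prepare(model, images)
  npos <- model$geo$npos
  Y_all <- diag(model$n_classes)[y, , drop = FALSE]
  st <- adam_state(model$params)
  n_batches <- max(1L, n %/% batch_size)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      order_idx <- if (is.null(sample_weights)) sample.int(n) else NULL
      for (b in seq_len(n_batches)) {
        idx <- if (is.null(sample_weights)) {
          order_idx[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
        } else {
          sample.int(n, batch_size, replace = TRUE, prob = sample_weights)
        }
        B <- length(idx)
        rows <- rep((idx - 1L) * npos, each = npos) + rep(seq_len(npos), B)
        Pb <- Pall[rows, , drop = FALSE]
        fw <- cnn_forward(model, Pb, B)
        gr <- cnn_backward(model, Pb, fw, Y_all[idx, , drop = FALSE])
        upd <- adam_update(model$params, gr, st, learning_rate)
        model$params <- upd$params; st <- upd$state
      }
    }
  })
  model
}

#' @keywords internal
cnn_predict <- function(model, images, batch = 64L) {
  if (is.matrix(images)) images <- list(images)
  n <- length(images)
  out <- matrix(NA_real_, n, model$n_classes)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    Pb <- cnn_prepare(model, images[idx])
    out[idx, ] <- cnn_forward(model, Pb, length(idx))$probs
  }
  out
}
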