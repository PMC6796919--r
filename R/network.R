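# Two-branch neural classifier over the SDP and linear inputs.
#
# Architecture: per-position concatenation of word + PoS + dependency
# embeddings (all tables fixed) -> additive Gaussian noise (training only)
# -> branch core (bidirectional LSTM with final-state concatenation, or
# parallel convolutions per window size with global max pooling) for each
# of the two inputs -> branch outputs concatenated -> dropout -> dense
# softmax over the six classes.
#
# The engine is written directly on BLAS matrix operations: forward pass,
# backpropagation (through time for the recurrent core) and an RMSprop
# optimizer. Padded positions are masked in the recurrent core (the state
# is carried through them unchanged); convolutions see zero vectors at
# padded positions, with one window per start position and the max pool
# restricted to content start positions (so trailing padding can never
# alter a branch output). Correctness of all gradients is checked against
# central finite differences in the test suite.

#' Network configuration
#'
#' Hyper-parameters of the two-branch classifier. Defaults follow the
#' system parameterization used throughout the package: Gaussian noise sd
#' 0.01, 128 LSTM units with dropout and recurrent dropout 0.4, 64
#' convolution filters with window sizes 3/4/5, dropout 0.4 before the
#' softmax, six output classes.
#'
#' @param branch_core `"bilstm"` or `"cnn"`.
#' @param noise_sd Standard deviation of the additive Gaussian input noise
#'   (training mode only).
#' @param lstm_units Hidden units per LSTM direction.
#' @param lstm_dropout,lstm_recurrent_dropout Input / recurrent dropout
#'   rates inside the LSTM (per-sequence masks, training only).
#' @param conv_filters Filters per convolution window size.
#' @param conv_windows Integer vector of convolution window sizes.
#' @param dropout_rate Dropout on the concatenated branch outputs.
#' @param n_classes Number of output classes (negative class first).
#' @return A `network_config` list.
#' @export
network_config <- function(branch_core = c("bilstm", "cnn"),
                           noise_sd = 0.01,
                           lstm_units = 128L,
                           lstm_dropout = 0.4,
                           lstm_recurrent_dropout = 0.4,
                           conv_filters = 64L,
                           conv_windows = c(3L, 4L, 5L),
                           dropout_rate = 0.4,
                           n_classes = 6L) {
  branch_core <- match.arg(branch_core)
  rates <- c(lstm_dropout, lstm_recurrent_dropout, dropout_rate)
  stopifnot(all(rates >= 0), all(rates < 1), all(conv_windows >= 1L),
            n_classes >= 2L, noise_sd >= 0, lstm_units >= 1L,
            conv_filters >= 1L)
  structure(list(
    branch_core = branch_core, noise_sd = noise_sd,
    lstm_units = as.integer(lstm_units),
    lstm_dropout = lstm_dropout,
    lstm_recurrent_dropout = lstm_recurrent_dropout,
    conv_filters = as.integer(conv_filters),
    conv_windows = as.integer(conv_windows),
    dropout_rate = dropout_rate,
    n_classes = as.integer(n_classes)
  ), class = "network_config")
}

sigm <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

branch_width <- function(cfg) {
  if (cfg$branch_core == "bilstm") 2L * cfg$lstm_units
  else cfg$conv_filters * length(cfg$conv_windows)
}

#' Build a two-branch network
#'
#' Initializes all weights (Glorot-uniform kernels, zero biases with the
#' LSTM forget-gate bias at 1) under the given seed and binds the fixed
#' embedding tables.
#'
#' @param cfg A [network_config()].
#' @param word_table,pos_table,dep_table `embedding_table`s (word table
#'   typically the corpus-vocabulary table of a `vocab_map`).
#' @param classes Label inventory; negative class must be first.
#' @param seed Integer seed for weight initialization.
#' @return An `sdprel_network` model handle.
#' @export
build_network <- function(cfg, word_table, pos_table, dep_table,
                          classes = cpr_classes(), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  if (length(classes) != cfg$n_classes) {
    stop(sprintf("config declares %d classes but %d labels supplied",
                 cfg$n_classes, length(classes)), call. = FALSE)
  }
  if (classes[1] != NEGATIVE_LABEL) {
    stop("the first class must be the negative (abstention) class", call. = FALSE)
  }
  dims <- c(word = ncol(word_table$vectors), pos = ncol(pos_table$vectors),
            dep = ncol(dep_table$vectors))
  d <- sum(dims)
  H <- cfg$lstm_units
  set.seed(seed)
  params <- list()
  for (branch in c("sdp", "lin")) {
    if (cfg$branch_core == "bilstm") {
      for (dir in c("fw", "bw")) {
        b <- rep(0, 4L * H)
        b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
        params[[paste(branch, dir, "Wx", sep = ".")]] <- glorot(d, 4L * H)
        params[[paste(branch, dir, "Wh", sep = ".")]] <- glorot(H, 4L * H)
        params[[paste(branch, dir, "b", sep = ".")]] <- matrix(b, 1L)
      }
    } else {
      for (w in cfg$conv_windows) {
        params[[paste(branch, "conv", w, "W", sep = ".")]] <-
          glorot(w * d, cfg$conv_filters)
        params[[paste(branch, "conv", w, "b", sep = ".")]] <-
          matrix(0, 1L, cfg$conv_filters)
      }
    }
  }
  D <- 2L * branch_width(cfg)
  params$dense.W <- glorot(D, cfg$n_classes)
  params$dense.b <- matrix(0, 1L, cfg$n_classes)
  structure(list(
    cfg = cfg,
    classes = classes,
    dims = dims,
    emb = list(word = word_table$vectors, pos = pos_table$vectors,
               dep = dep_table$vectors),
    params = params,
    opt = NULL,
    seed = seed
  ), class = "sdprel_network")
}

#' @export
print.sdprel_network <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<sdprel_network> core=%s, input dim %d (w%d+p%d+d%d), %d trainable parameters\n",
              x$cfg$branch_core, sum(x$dims), x$dims["word"], x$dims["pos"],
              x$dims["dep"], n_par))
  invisible(x)
}

# Embedding lookup: index matrices (n x T, 0-based, 0 = padding) to a
# n x (T*d) matrix with per-position concatenated word/pos/dep vectors.
embed_input <- function(model, widx, pidx, didx) {
  n <- nrow(widx); Tn <- ncol(widx)
  dw <- model$dims["word"]; dp <- model$dims["pos"]; dd <- model$dims["dep"]
  d <- dw + dp + dd
  X <- matrix(0, n, Tn * d)
  for (t in seq_len(Tn)) {
    off <- (t - 1L) * d
    X[, off + seq_len(dw)] <- model$emb$word[widx[, t] + 1L, , drop = FALSE]
    X[, off + dw + seq_len(dp)] <- model$emb$pos[pidx[, t] + 1L, , drop = FALSE]
    X[, off + dw + dp + seq_len(dd)] <- model$emb$dep[didx[, t] + 1L, , drop = FALSE]
  }
  X
}

GATES <- function(H) list(i = seq_len(H), f = H + seq_len(H),
                          g = 2L * H + seq_len(H), o = 3L * H + seq_len(H))

# One LSTM direction over timesteps `steps` (a permutation of 1..T giving
# the processing order). Masked positions carry the previous state.
lstm_run <- function(Wx, Wh, b, X, M, d, H, steps, Dx = NULL, Dh = NULL,
                     keep_cache = FALSE) {
  n <- nrow(M)
  Tn <- length(steps)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  gs <- GATES(H)
  cache <- NULL
  if (keep_cache) {
    cache <- list(
      i = array(0, c(n, H, Tn)), f = array(0, c(n, H, Tn)),
      g = array(0, c(n, H, Tn)), o = array(0, c(n, H, Tn)),
      tc = array(0, c(n, H, Tn)), c_prev = array(0, c(n, H, Tn)),
      xt = array(0, c(n, d, Tn)), hd = array(0, c(n, H, Tn)),
      steps = steps
    )
  }
  bmat <- matrix(b, n, 4L * H, byrow = TRUE)
  for (k in seq_len(Tn)) {
    t <- steps[k]
    xt <- X[, (t - 1L) * d + seq_len(d), drop = FALSE]
    if (!is.null(Dx)) xt <- xt * Dx
    hd <- if (!is.null(Dh)) h * Dh else h
    z <- xt %*% Wx + hd %*% Wh + bmat
    gi <- sigm(z[, gs$i, drop = FALSE])
    gf <- sigm(z[, gs$f, drop = FALSE])
    gg <- tanh(z[, gs$g, drop = FALSE])
    go <- sigm(z[, gs$o, drop = FALSE])
    cn <- gf * cc + gi * gg
    tc <- tanh(cn)
    hn <- go * tc
    m <- M[, t]
    if (keep_cache) {
      cache$i[, , k] <- gi; cache$f[, , k] <- gf
      cache$g[, , k] <- gg; cache$o[, , k] <- go
      cache$tc[, , k] <- tc; cache$c_prev[, , k] <- cc
      cache$xt[, , k] <- xt; cache$hd[, , k] <- hd
    }
    cc <- m * cn + (1 - m) * cc
    h <- m * hn + (1 - m) * h
  }
  list(h = h, cache = cache)
}

# Backprop through time for one direction; returns parameter gradients.
# Dh is the recurrent-dropout mask (hd = h_prev * Dh in the forward pass).
lstm_backprop <- function(Wx, Wh, cache, M, dh_final, H, Dh = NULL) {
  n <- nrow(dh_final)
  steps <- cache$steps
  Tn <- length(steps)
  dWx <- matrix(0, dim(cache$xt)[2], 4L * H)
  dWh <- matrix(0, H, 4L * H)
  db <- matrix(0, 1L, 4L * H)
  dh <- dh_final
  dc <- matrix(0, n, H)
  for (k in rev(seq_len(Tn))) {
    m <- M[, steps[k]]
    gi <- cache$i[, , k, drop = FALSE]; dim(gi) <- c(n, H)
    gf <- cache$f[, , k, drop = FALSE]; dim(gf) <- c(n, H)
    gg <- cache$g[, , k, drop = FALSE]; dim(gg) <- c(n, H)
    go <- cache$o[, , k, drop = FALSE]; dim(go) <- c(n, H)
    tc <- cache$tc[, , k, drop = FALSE]; dim(tc) <- c(n, H)
    cp <- cache$c_prev[, , k, drop = FALSE]; dim(cp) <- c(n, H)
    xt <- cache$xt[, , k, drop = FALSE]; dim(xt) <- c(n, dim(cache$xt)[2])
    hd <- cache$hd[, , k, drop = FALSE]; dim(hd) <- c(n, H)
    dhn <- dh * m
    dh_prev <- dh * (1 - m)
    dcn <- dc * m
    dc_prev <- dc * (1 - m)
    do_ <- dhn * tc
    dcn <- dcn + dhn * go * (1 - tc * tc)
    di <- dcn * gg
    df <- dcn * cp
    dg <- dcn * gi
    dc <- dc_prev + dcn * gf
    dz <- cbind(di * gi * (1 - gi), df * gf * (1 - gf),
                dg * (1 - gg * gg), do_ * go * (1 - go))
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(hd, dz)
    db <- db + colSums(dz)
    dhd <- dz %*% t(Wh)
    if (!is.null(Dh)) dhd <- dhd * Dh
    dh <- dh_prev + dhd
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

# Forward pass of one branch. Returns the branch output and (optionally)
# everything needed for the backward pass.
branch_forward <- function(model, branch, X, M, training, keep_cache) {
  cfg <- model$cfg
  d <- sum(model$dims)
  n <- nrow(M); Tn <- ncol(M)
  if (cfg$branch_core == "bilstm") {
    H <- cfg$lstm_units
    Dx_fw <- Dx_bw <- Dh_fw <- Dh_bw <- NULL
    if (training && cfg$lstm_dropout > 0) {
      p <- cfg$lstm_dropout
      Dx_fw <- matrix(stats::rbinom(n * d, 1L, 1 - p) / (1 - p), n, d)
      Dx_bw <- matrix(stats::rbinom(n * d, 1L, 1 - p) / (1 - p), n, d)
    }
    if (training && cfg$lstm_recurrent_dropout > 0) {
      p <- cfg$lstm_recurrent_dropout
      Dh_fw <- matrix(stats::rbinom(n * H, 1L, 1 - p) / (1 - p), n, H)
      Dh_bw <- matrix(stats::rbinom(n * H, 1L, 1 - p) / (1 - p), n, H)
    }
    pw <- function(nm) model$params[[paste(branch, nm, sep = ".")]]
    fw <- lstm_run(pw("fw.Wx"), pw("fw.Wh"), pw("fw.b"), X, M, d, H,
                   steps = seq_len(Tn), Dx = Dx_fw, Dh = Dh_fw,
                   keep_cache = keep_cache)
    bw <- lstm_run(pw("bw.Wx"), pw("bw.Wh"), pw("bw.b"), X, M, d, H,
                   steps = rev(seq_len(Tn)), Dx = Dx_bw, Dh = Dh_bw,
                   keep_cache = keep_cache)
    list(out = cbind(fw$h, bw$h),
         cache = if (keep_cache) list(fw = fw$cache, bw = bw$cache,
                                      Dx = list(fw = Dx_fw, bw = Dx_bw),
                                      Dh = list(fw = Dh_fw, bw = Dh_bw),
                                      M = M) else NULL)
  } else {
    # one window per start position, implicitly zero-padded on the right
    # ("same"-style); the max pool only admits windows starting at a
    # content position, so trailing padding cannot alter the branch output
    Fd <- cfg$conv_filters
    wmax <- max(cfg$conv_windows)
    Xp <- if (wmax > 1L) cbind(X, matrix(0, n, (wmax - 1L) * d)) else X
    outs <- list()
    caches <- list()
    for (w in cfg$conv_windows) {
      W <- model$params[[paste(branch, "conv", w, "W", sep = ".")]]
      bb <- model$params[[paste(branch, "conv", w, "b", sep = ".")]]
      pooled <- matrix(-Inf, n, Fd)
      argp <- matrix(0L, n, Fd)
      acts <- if (keep_cache) array(0, c(n, Fd, Tn)) else NULL
      for (p in seq_len(Tn)) {
        cols <- (p - 1L) * d + seq_len(w * d)
        z <- Xp[, cols, drop = FALSE] %*% W
        z <- sweep(z, 2L, bb, "+")
        a <- z * (z > 0)
        if (keep_cache) acts[, , p] <- a
        valid <- M[, p] == 1
        upd <- (a > pooled) & valid
        pooled[upd] <- a[upd]
        argp[upd] <- p
      }
      none <- !is.finite(pooled)
      pooled[none] <- 0
      outs[[as.character(w)]] <- pooled
      caches[[as.character(w)]] <- list(argp = argp, acts = acts, w = w)
    }
    list(out = do.call(cbind, outs),
         cache = if (keep_cache) list(windows = caches, Xp = Xp, Tn = Tn) else NULL)
  }
}

branch_backprop <- function(model, branch, cache, dOut, grads) {
  cfg <- model$cfg
  d <- sum(model$dims)
  if (cfg$branch_core == "bilstm") {
    H <- cfg$lstm_units
    for (dir in c("fw", "bw")) {
      sel <- if (dir == "fw") seq_len(H) else H + seq_len(H)
      dh <- dOut[, sel, drop = FALSE]
      g <- lstm_backprop(
        model$params[[paste(branch, dir, "Wx", sep = ".")]],
        model$params[[paste(branch, dir, "Wh", sep = ".")]],
        cache[[dir]], cache$M, dh, H, Dh = cache$Dh[[dir]]
      )
      grads[[paste(branch, dir, "Wx", sep = ".")]] <- g$dWx
      grads[[paste(branch, dir, "Wh", sep = ".")]] <- g$dWh
      grads[[paste(branch, dir, "b", sep = ".")]] <- g$db
    }
  } else {
    Fd <- cfg$conv_filters
    off <- 0L
    for (w in cfg$conv_windows) {
      cw <- cache$windows[[as.character(w)]]
      dpool <- dOut[, off + seq_len(Fd), drop = FALSE]
      off <- off + Fd
      dW <- matrix(0, w * d, Fd)
      db <- matrix(0, 1L, Fd)
      for (p in seq_len(cache$Tn)) {
        sel <- cw$argp == p
        if (!any(sel)) next
        a <- cw$acts[, , p, drop = FALSE]
        dim(a) <- dim(sel)
        dz <- dpool * sel * (a > 0)
        cols <- (p - 1L) * d + seq_len(w * d)
        dW <- dW + crossprod(cache$Xp[, cols, drop = FALSE], dz)
        db <- db + colSums(dz)
      }
      grads[[paste(branch, "conv", w, "W", sep = ".")]] <- dW
      grads[[paste(branch, "conv", w, "b", sep = ".")]] <- db
    }
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass over an encoded batch (index matrices).
nn_forward <- function(model, batch, training = FALSE, keep_cache = FALSE) {
  Xs <- embed_input(model, batch$sdp_word, batch$sdp_pos, batch$sdp_dep)
  Xl <- embed_input(model, batch$lin_word, batch$lin_pos, batch$lin_dep)
  Ms <- (batch$sdp_word > 0L) * 1
  Ml <- (batch$lin_word > 0L) * 1
  if (training && model$cfg$noise_sd > 0) {
    Xs <- Xs + stats::rnorm(length(Xs), sd = model$cfg$noise_sd)
    Xl <- Xl + stats::rnorm(length(Xl), sd = model$cfg$noise_sd)
  }
  bs <- branch_forward(model, "sdp", Xs, Ms, training, keep_cache)
  bl <- branch_forward(model, "lin", Xl, Ml, training, keep_cache)
  Hc <- cbind(bs$out, bl$out)
  Ddrop <- NULL
  if (training && model$cfg$dropout_rate > 0) {
    p <- model$cfg$dropout_rate
    Ddrop <- matrix(stats::rbinom(length(Hc), 1L, 1 - p) / (1 - p),
                    nrow(Hc), ncol(Hc))
    Hc <- Hc * Ddrop
  }
  logits <- Hc %*% model$params$dense.W
  logits <- sweep(logits, 2L, model$params$dense.b, "+")
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = if (keep_cache) list(sdp = bs$cache, lin = bl$cache,
                                    Hc = Hc, Ddrop = Ddrop) else NULL)
}

# Backward pass: dlogits (n x C) to gradients for every parameter.
nn_backward <- function(model, fwd, dlogits) {
  grads <- list()
  grads$dense.W <- crossprod(fwd$cache$Hc, dlogits)
  grads$dense.b <- colSums(dlogits)
  dH <- dlogits %*% t(model$params$dense.W)
  if (!is.null(fwd$cache$Ddrop)) dH <- dH * fwd$cache$Ddrop
  bwidth <- branch_width(model$cfg)
  grads <- branch_backprop(model, "sdp", fwd$cache$sdp,
                           dH[, seq_len(bwidth), drop = FALSE], grads)
  grads <- branch_backprop(model, "lin", fwd$cache$lin,
                           dH[, bwidth + seq_len(bwidth), drop = FALSE], grads)
  grads
}

# Weighted categorical cross-entropy; returns loss and dlogits.
xent_loss <- function(probs, y_idx, weights) {
  n <- nrow(probs)
  p_gold <- probs[cbind(seq_len(n), y_idx)]
  loss <- sum(weights * -log(pmax(p_gold, 1e-12))) / n
  Y <- matrix(0, n, ncol(probs))
  Y[cbind(seq_len(n), y_idx)] <- 1
  dlogits <- (probs - Y) * (weights / n)
  list(loss = loss, dlogits = dlogits)
}

rmsprop_step <- function(model, grads, lr = 1e-3, rho = 0.9, eps = 1e-7) {
  if (is.null(model$opt)) {
    model$opt <- lapply(model$params, function(p) array(0, dim(p)))
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- rho * model$opt[[nm]] + (1 - rho) * g * g
    model$opt[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] - lr * g / (sqrt(v) + eps)
  }
  model
}

#' Predict class probabilities
#'
#' Runs the network in inference mode (Gaussian noise and dropout
#' inactive): deterministic for fixed weights and inputs, each row a
#' probability distribution over the class inventory.
#'
#' @param model An `sdprel_network`.
#' @param batch An `encoded_batch` (or any list of index matrices with the
#'   same fields).
#' @param chunk Number of instances evaluated per internal block.
#' @return Numeric matrix, one row per instance, columns named by class.
#' @export
predict_proba <- function(model, batch, chunk = 512L) {
  n <- n_encoded(batch)
  if (max(batch$sdp_word, batch$lin_word) + 1L > nrow(model$emb$word) ||
      max(batch$sdp_pos, batch$lin_pos) + 1L > nrow(model$emb$pos) ||
      max(batch$sdp_dep, batch$lin_dep) + 1L > nrow(model$emb$dep)) {
    stop("encoded index outside embedding table range", call. = FALSE)
  }
  out <- matrix(0, n, model$cfg$n_classes,
                dimnames = list(NULL, model$classes))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    out[idx, ] <- nn_forward(model, subset_batch(batch, idx),
                             training = FALSE)$probs
  }
  out
}
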