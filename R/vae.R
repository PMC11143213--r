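#' Embedder (VAE) configuration
#'
#' The variational autoencoder maps the 536-dimensional concatenated feature
#' vector through two fully connected hidden layers (batch-normalised, with
#' dropout) to a 32-dimensional Gaussian latent; the decoder mirrors the
#' encoder and reconstructs both feature blocks through softmax heads. The
#' loss is the weighted sum of two cross-entropy reconstruction terms and a
#' KL term, with weights derived from the dimensions:
#' `w_A = alpha / ln(dim(X_A))`, `w_T = (1 - alpha) / ln(dim(X_T))`,
#' `w_KL = beta / dim(Z)`; they are always recomputed from the actual
#' dimensions, never hard-coded.
#'
#' @param hidden_sizes Integer vector of hidden layer widths (default
#'   `c(512, 512)`).
#' @param latent_dim Latent dimension (default 32).
#' @param dropout_p Dropout probability after each hidden layer (default 0.2).
#' @param alpha Share of reconstruction weight given to the abundance
#'   histogram (default 0.1).
#' @param beta KL weight numerator (default 0.015).
#' @param batch_size,learning_rate,max_epochs,patience Adam training
#'   hyperparameters; early stopping monitors a held-out split.
#' @param min_delta Smallest validation-loss drop that counts as progress for
#'   early stopping; training stops after `patience` epochs without one and
#'   the weights of the last significant improvement are kept. Guards against
#'   the long creeping-loss tail in which the latent overfits record-level
#'   detail (default 1e-3).
#' @param weight_decay L2 penalty applied through the optimiser (decoupled,
#'   AdamW-style); regularises against latent overfitting on small record
#'   sets (default 1e-4).
#' @param val_fraction Held-out fraction for early stopping (default 0.1).
#' @param seed Integer seed; training is reproducible per device.
#' @param as_printed Evaluate the reconstruction terms without the
#'   cross-entropy minus sign (the literal published formula) instead of the
#'   true cross-entropy; audit switch, default `FALSE`.
#' @param uniform_fallback Sample training batches uniformly when every
#'   record weight is zero (default `FALSE`: that situation errors).
#'
#' @return An `embedder_config` list.
#' @export
embedder_config <- function(hidden_sizes = c(512, 512), latent_dim = 32,
                            dropout_p = 0.2, alpha = 0.1, beta = 0.015,
                            batch_size = 256, learning_rate = 1e-3,
                            max_epochs = 500, patience = 10,
                            min_delta = 1e-3, weight_decay = 1e-4,
                            val_fraction = 0.1, seed = 1L,
                            as_printed = FALSE, uniform_fallback = FALSE) {
  stopifnot(alpha > 0, alpha < 1, latent_dim > 0, dropout_p >= 0,
            dropout_p < 1, length(hidden_sizes) >= 1, all(hidden_sizes > 0),
            val_fraction > 0, val_fraction < 0.5)
  structure(
    list(
      hidden_sizes = as.integer(hidden_sizes),
      latent_dim = as.integer(latent_dim),
      dropout_p = dropout_p, alpha = alpha, beta = beta,
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      min_delta = min_delta, weight_decay = weight_decay,
      val_fraction = val_fraction, seed = as.integer(seed),
      as_printed = isTRUE(as_printed),
      uniform_fallback = isTRUE(uniform_fallback)
    ),
    class = "embedder_config"
  )
}

#' Loss weights derived from feature dimensions
#'
#' @param dim_a,dim_t,latent_dim Feature-block and latent dimensions.
#' @param alpha,beta Mixing parameters.
#' @return Named list `w_a`, `w_t`, `w_kl`.
#' @export
loss_weights <- function(dim_a, dim_t, latent_dim, alpha = 0.1, beta = 0.015) {
  list(w_a = alpha / log(dim_a), w_t = (1 - alpha) / log(dim_t),
       w_kl = beta / latent_dim)
}

as_row <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Embedding loss components
#'
#' Computes the per-sample reconstruction cross-entropies
#' `L_A = -sum(X_A * ln(X̂_A + 1e-9))`, `L_T = -sum(X_T * ln(X̂_T + 1e-9))`,
#' the KL term `L_KL = -sum(0.5 * (1 + ln(sigma) - mu^2 - sigma))` (evaluated
#' in the variance `sigma`, which vanishes exactly at the standard-normal
#' prior), and the weighted total. Values are averaged over rows.
#'
#' @param x_a,x_t Target feature blocks (vectors or row matrices).
#' @param xhat_a,xhat_t Softmax-normalised reconstructions.
#' @param mu,sigma Latent Gaussian parameters (`sigma` is the variance and
#'   must be positive).
#' @param config An [embedder_config()] (supplies `alpha`, `beta`,
#'   `as_printed`).
#'
#' @return One-row tibble with `l_a`, `l_t`, `l_kl`, `w_a`, `w_t`, `w_kl`,
#'   `total`.
#' @export
loss_components <- function(x_a, x_t, xhat_a, xhat_t, mu, sigma,
                            config = embedder_config()) {
  x_a <- as_row(x_a); x_t <- as_row(x_t)
  xhat_a <- as_row(xhat_a); xhat_t <- as_row(xhat_t)
  mu <- as_row(mu); sigma <- as_row(sigma)
  if (!identical(dim(x_a), dim(xhat_a)) || !identical(dim(x_t), dim(xhat_t)) ||
      !identical(dim(mu), dim(sigma))) {
    abort("dimension mismatch between targets, reconstructions or latents")
  }
  if (any(sigma <= 0)) abort("`sigma` must be positive")
  sign <- if (config$as_printed) 1 else -1
  l_a <- mean(sign * rowSums(x_a * log(xhat_a + 1e-9)))
  l_t <- mean(sign * rowSums(x_t * log(xhat_t + 1e-9)))
  l_kl <- mean(-rowSums(0.5 * (1 + log(sigma) - mu^2 - sigma)))
  w <- loss_weights(ncol(x_a), ncol(x_t), ncol(mu), config$alpha, config$beta)
  tibble(l_a = l_a, l_t = l_t, l_kl = l_kl,
         w_a = w$w_a, w_t = w$w_t, w_kl = w$w_kl,
         total = w$w_a * l_a + w$w_t * l_t + w$w_kl * l_kl)
}

#' Weighted-with-replacement record sampler
#'
#' Mirrors a weighted random sampler used to balance training batches: records
#' are drawn with replacement with probability proportional to their sampling
#' weight. The returned closure carries its own RNG stream so successive
#' draws are reproducible under the seed and independent of the caller's RNG.
#'
#' @param weights Non-negative record weights (not all zero unless
#'   `uniform_fallback`).
#' @param seed Integer seed.
#' @param uniform_fallback Draw uniformly if all weights are zero.
#'
#' @return `function(n)` returning `n` record indices.
#' @export
make_weighted_sampler <- function(weights, seed = 1L,
                                  uniform_fallback = FALSE) {
  if (any(weights < 0)) abort("weights must be non-negative")
  if (all(weights == 0)) {
    if (!uniform_fallback) {
      abort(paste0("all sampling weights are zero; set `uniform_fallback = ",
                   "TRUE` to draw uniformly"))
    }
    weights <- rep(1, length(weights))
  }
  state <- NULL
  k <- length(weights)
  function(n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    out <- sample.int(k, n, replace = TRUE, prob = weights)
    state <<- get(".Random.seed", envir = globalenv())
    out
  }
}

## ---- network internals ----------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

init_linear <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

init_block <- function(n_in, n_out) {
  c(init_linear(n_in, n_out),
    list(g = rep(1, n_out), be = numeric(n_out)))
}

init_stats <- function(n_out) list(rm = numeric(n_out), rv = rep(1, n_out))

bn_eps <- 1e-5
bn_momentum <- 0.1

# hidden block forward: linear -> batchnorm -> relu -> dropout
block_forward <- function(h, p, st, dropout_p, training) {
  a <- h %*% p$W + rep(p$b, each = nrow(h))
  if (training) {
    m <- colMeans(a)
    v <- colMeans(a^2) - m^2
    xhat <- (a - rep(m, each = nrow(a))) / rep(sqrt(v + bn_eps), each = nrow(a))
    st$rm <- (1 - bn_momentum) * st$rm + bn_momentum * m
    st$rv <- (1 - bn_momentum) * st$rv + bn_momentum * v
  } else {
    v <- st$rv
    xhat <- (a - rep(st$rm, each = nrow(a))) /
      rep(sqrt(st$rv + bn_eps), each = nrow(a))
  }
  y <- xhat * rep(p$g, each = nrow(a)) + rep(p$be, each = nrow(a))
  r <- pmax(y, 0)
  if (training && dropout_p > 0) {
    mask <- matrix((runif(length(r)) >= dropout_p) / (1 - dropout_p),
                   nrow(r), ncol(r))
    out <- r * mask
  } else {
    mask <- NULL
    out <- r
  }
  list(out = out, cache = list(h = h, xhat = xhat, v = v, y = y, mask = mask),
       stats = st)
}

block_backward <- function(dout, p, cache) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  dy <- dout * (cache$y > 0)
  n <- nrow(dy)
  dg <- colSums(dy * cache$xhat)
  dbe <- colSums(dy)
  dxhat <- dy * rep(p$g, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  da <- (dxhat - rep(s1 / n, each = n) -
           cache$xhat * rep(s2 / n, each = n)) /
    rep(sqrt(cache$v + bn_eps), each = n)
  list(
    dh = da %*% t(p$W),
    grads = list(W = crossprod(cache$h, da), b = colSums(da), g = dg, be = dbe)
  )
}

init_embedder_params <- function(dim_in, hidden, latent, dim_a, dim_t) {
  H <- length(hidden)
  enc <- vector("list", H); enc_st <- vector("list", H)
  sizes <- c(dim_in, hidden)
  for (i in seq_len(H)) {
    enc[[i]] <- init_block(sizes[i], sizes[i + 1])
    enc_st[[i]] <- init_stats(sizes[i + 1])
  }
  dec <- vector("list", H); dec_st <- vector("list", H)
  dsizes <- c(latent, rev(hidden))
  for (i in seq_len(H)) {
    dec[[i]] <- init_block(dsizes[i], dsizes[i + 1])
    dec_st[[i]] <- init_stats(dsizes[i + 1])
  }
  top <- rev(hidden)[1]
  list(
    theta = list(enc = enc, mu = init_linear(tail_one(hidden), latent),
                 sg = init_linear(tail_one(hidden), latent),
                 dec = dec, out_a = init_linear(top, dim_a),
                 out_t = init_linear(top, dim_t)),
    stats = list(enc = enc_st, dec = dec_st)
  )
}

tail_one <- function(x) x[length(x)]

embedder_forward <- function(theta, stats, x, cfg, training) {
  H <- length(theta$enc)
  caches <- list(enc = vector("list", H), dec = vector("list", H))
  h <- x
  for (i in seq_len(H)) {
    fw <- block_forward(h, theta$enc[[i]], stats$enc[[i]], cfg$dropout_p,
                        training)
    h <- fw$out; caches$enc[[i]] <- fw$cache; stats$enc[[i]] <- fw$stats
  }
  mu <- h %*% theta$mu$W + rep(theta$mu$b, each = nrow(h))
  s <- h %*% theta$sg$W + rep(theta$sg$b, each = nrow(h))
  sigma <- softplus(s) + 1e-8
  if (training) {
    eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
    z <- mu + sqrt(sigma) * eps
  } else {
    eps <- NULL
    z <- mu
  }
  g <- z
  for (i in seq_len(H)) {
    fw <- block_forward(g, theta$dec[[i]], stats$dec[[i]], cfg$dropout_p,
                        training)
    g <- fw$out; caches$dec[[i]] <- fw$cache; stats$dec[[i]] <- fw$stats
  }
  logit_a <- g %*% theta$out_a$W + rep(theta$out_a$b, each = nrow(g))
  logit_t <- g %*% theta$out_t$W + rep(theta$out_t$b, each = nrow(g))
  list(
    h_enc = h, mu = mu, s = s, sigma = sigma, eps = eps, z = z, g = g,
    yhat_a = row_softmax(logit_a), yhat_t = row_softmax(logit_t),
    caches = caches, stats = stats
  )
}

embedder_step <- function(theta, stats, xa, xt, cfg, w) {
  B <- nrow(xa)
  fw <- embedder_forward(theta, stats, cbind(xa, xt), cfg, training = TRUE)
  sign <- if (cfg$as_printed) 1 else -1
  l_a <- mean(sign * rowSums(xa * log(fw$yhat_a + 1e-9)))
  l_t <- mean(sign * rowSums(xt * log(fw$yhat_t + 1e-9)))
  l_kl <- mean(-rowSums(0.5 * (1 + log(fw$sigma) - fw$mu^2 - fw$sigma)))
  total <- w$w_a * l_a + w$w_t * l_t + w$w_kl * l_kl
  if (!is.finite(total)) {
    abort(paste0("non-finite training loss (l_a=", l_a, ", l_t=", l_t,
                 ", l_kl=", l_kl, "); try a lower learning rate"))
  }

  grads <- list()
  # softmax + cross-entropy heads: d/dlogit = (rowsum(target) * yhat - target)
  dlog_a <- -sign * (w$w_a / B) * (fw$yhat_a * rowSums(xa) - xa)
  dlog_t <- -sign * (w$w_t / B) * (fw$yhat_t * rowSums(xt) - xt)
  grads$out_a <- list(W = crossprod(fw$g, dlog_a), b = colSums(dlog_a))
  grads$out_t <- list(W = crossprod(fw$g, dlog_t), b = colSums(dlog_t))
  dg <- dlog_a %*% t(theta$out_a$W) + dlog_t %*% t(theta$out_t$W)
  H <- length(theta$dec)
  grads$dec <- vector("list", H)
  for (i in rev(seq_len(H))) {
    bw <- block_backward(dg, theta$dec[[i]], fw$caches$dec[[i]])
    grads$dec[[i]] <- bw$grads
    dg <- bw$dh
  }
  dz <- dg
  dmu <- dz + (w$w_kl / B) * fw$mu
  dsigma <- dz * fw$eps / (2 * sqrt(fw$sigma)) -
    (w$w_kl / B) * 0.5 * (1 / fw$sigma - 1)
  ds <- dsigma * sigmoid(fw$s)
  grads$mu <- list(W = crossprod(fw$h_enc, dmu), b = colSums(dmu))
  grads$sg <- list(W = crossprod(fw$h_enc, ds), b = colSums(ds))
  dh <- dmu %*% t(theta$mu$W) + ds %*% t(theta$sg$W)
  grads$enc <- vector("list", H)
  for (i in rev(seq_len(H))) {
    bw <- block_backward(dh, theta$enc[[i]], fw$caches$enc[[i]])
    grads$enc[[i]] <- bw$grads
    dh <- bw$dh
  }
  list(grads = grads, stats = fw$stats,
       loss = tibble(l_a = l_a, l_t = l_t, l_kl = l_kl, total = total))
}

# Adam over the nested parameter list
adam_update <- function(theta, grads, state, lr, t, wd = 0,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  walk <- function(th, gr, st) {
    if (is.list(th) && !is.null(names(th)) &&
        all(names(th) %in% c("W", "b", "g", "be"))) {
      for (nm in names(th)) {
        if (is.null(st)) st <- list()
        if (is.null(st[[nm]])) st[[nm]] <- list(m = th[[nm]] * 0,
                                                v = th[[nm]] * 0)
        st[[nm]]$m <- b1 * st[[nm]]$m + (1 - b1) * gr[[nm]]
        st[[nm]]$v <- b2 * st[[nm]]$v + (1 - b2) * gr[[nm]]^2
        mhat <- st[[nm]]$m / (1 - b1^t)
        vhat <- st[[nm]]$v / (1 - b2^t)
        th[[nm]] <- th[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        if (nm == "W" && wd > 0) th[[nm]] <- th[[nm]] - lr * wd * th[[nm]]
      }
      list(th = th, st = st)
    } else {
      if (is.null(st)) {
        st <- vector("list", length(th))
        names(st) <- names(th)
      }
      keys <- if (is.null(names(th))) seq_along(th) else names(th)
      for (i in keys) {
        r <- walk(th[[i]], gr[[i]], st[[i]])
        th[[i]] <- r$th; st[[i]] <- r$st
      }
      list(th = th, st = st)
    }
  }
  walk(theta, grads, state)
}

eval_loss <- function(theta, stats, xa, xt, cfg, w) {
  fw <- embedder_forward(theta, stats, cbind(xa, xt), cfg, training = FALSE)
  loss_components(xa, xt, fw$yhat_a, fw$yhat_t, fw$mu, fw$sigma,
                  config = cfg)$total
}

#' Train the barcode embedder
#'
#' Trains the VAE on non-flagged feature records with abundance-balanced
#' weighted sampling (batches drawn with replacement proportional to
#' `max(x_a)^2`), Adam optimisation and early stopping on a held-out split.
#' Training is deterministic under `config$seed` on a given device.
#'
#' @param features Tibble from [barcode_features()], or a list from
#'   [feature_matrix()].
#' @param config An [embedder_config()].
#' @param weighted Use weighted sampling (default `TRUE`); `FALSE` draws
#'   training batches uniformly (for ablation).
#'
#' @return A `linkbin_embedder` object with the trained parameters, the
#'   per-epoch loss log (see [tidy.linkbin_embedder()]) and the configuration.
#' @export
train_embedder <- function(features, config = embedder_config(),
                           weighted = TRUE) {
  fm <- if (is.list(features) && !is.data.frame(features) &&
            !is.null(features$x)) features else feature_matrix(features)
  x <- fm$x
  n <- nrow(x)
  if (n < 2 * config$batch_size) {
    config$batch_size <- max(2L, as.integer(floor(n / 4)))
  }
  dim_a <- fm$dim_a; dim_t <- fm$dim_t
  w <- loss_weights(dim_a, dim_t, config$latent_dim, config$alpha, config$beta)

  with_seed(config$seed, {
    net <- init_embedder_params(dim_a + dim_t, config$hidden_sizes,
                                config$latent_dim, dim_a, dim_t)
    theta <- net$theta; stats <- net$stats
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)
    wt <- if (weighted) fm$weight[train_idx] else rep(1, length(train_idx))
    if (all(wt == 0)) {
      if (!config$uniform_fallback) {
        abort(paste0("all sampling weights are zero; set `uniform_fallback",
                     " = TRUE` in embedder_config() to sample uniformly"))
      }
      wt <- rep(1, length(train_idx))
    }
    xa <- x[, seq_len(dim_a), drop = FALSE]
    xt <- x[, dim_a + seq_len(dim_t), drop = FALSE]

    adam_state <- NULL
    step <- 0L
    best <- list(val = Inf, theta = theta, stats = stats, epoch = 0L)
    wait <- 0L
    log <- vector("list", config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      order <- train_idx[sample.int(length(train_idx), length(train_idx),
                                    replace = TRUE, prob = wt)]
      losses <- list()
      for (b0 in seq(1, length(order), by = config$batch_size)) {
        idx <- order[b0:min(b0 + config$batch_size - 1L, length(order))]
        if (length(idx) < 2) next  # batch norm needs >= 2 rows
        st <- embedder_step(theta, stats,
                            xa[idx, , drop = FALSE], xt[idx, , drop = FALSE],
                            config, w)
        stats <- st$stats
        step <- step + 1L
        up <- adam_update(theta, st$grads, adam_state, config$learning_rate,
                          step, config$weight_decay)
        theta <- up$th; adam_state <- up$st
        losses[[length(losses) + 1L]] <- st$loss
      }
      ep <- dplyr::summarise(dplyr::bind_rows(losses),
                             dplyr::across(dplyr::everything(), mean))
      val <- eval_loss(theta, stats, xa[val_idx, , drop = FALSE],
                       xt[val_idx, , drop = FALSE], config, w)
      log[[epoch]] <- dplyr::mutate(ep, epoch = epoch, val_total = val)
      if (val < best$val - config$min_delta) {
        best <- list(val = val, theta = theta, stats = stats, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(
      list(
        theta = best$theta, stats = best$stats, config = config,
        weights = w, dim_a = dim_a, dim_t = dim_t,
        log = dplyr::bind_rows(log) |>
          dplyr::select("epoch", dplyr::everything()),
        best_epoch = best$epoch, val_loss = best$val,
        n_train = length(train_idx), n_val = n_val
      ),
      class = "linkbin_embedder"
    )
  })
}

#' @export
print.linkbin_embedder <- function(x, ...) {
  cat("<linkbin_embedder> ", x$dim_a, "+", x$dim_t, " -> ",
      paste(x$config$hidden_sizes, collapse = "/"), " -> ",
      x$config$latent_dim, " | best epoch ", x$best_epoch,
      " | validation loss ", signif(x$val_loss, 6), "\n", sep = "")
  invisible(x)
}

#' Embed barcodes into the latent space
#'
#' Deterministic evaluation pass: dropout disabled, batch statistics replaced
#' by running averages, and the latent mean `mu` (not a sample) returned per
#' record. Flagged records are excluded and reported.
#'
#' @param embedder A trained `linkbin_embedder`.
#' @param features Tibble from [barcode_features()] or a [feature_matrix()]
#'   list.
#'
#' @return Numeric matrix (records x latent_dim) with barcode rownames;
#'   excluded barcodes in `attr(, "excluded")`.
#' @export
embed_barcodes <- function(embedder, features) {
  fm <- if (is.list(features) && !is.data.frame(features) &&
            !is.null(features$x)) features else feature_matrix(features)
  excluded <- character()
  if (is.data.frame(features) && any(features$flagged)) {
    excluded <- features$barcode[features$flagged]
    message(length(excluded), " flagged record(s) excluded from embedding")
  }
  fw <- embedder_forward(embedder$theta, embedder$stats, fm$x,
                         embedder$config, training = FALSE)
  mu <- fw$mu
  rownames(mu) <- fm$barcode
  attr(mu, "excluded") <- excluded
  mu
}

#' @describeIn embed_barcodes Reconstruct inputs and loss components for a
#'   feature matrix under the trained model (evaluation mode).
#' @export
embedder_reconstruct <- function(embedder, features) {
  fm <- if (is.list(features) && !is.data.frame(features) &&
            !is.null(features$x)) features else feature_matrix(features)
  xa <- fm$x[, seq_len(embedder$dim_a), drop = FALSE]
  xt <- fm$x[, embedder$dim_a + seq_len(embedder$dim_t), drop = FALSE]
  fw <- embedder_forward(embedder$theta, embedder$stats, fm$x,
                         embedder$config, training = FALSE)
  list(
    xhat_a = fw$yhat_a, xhat_t = fw$yhat_t, mu = fw$mu, sigma = fw$sigma,
    loss = loss_components(xa, xt, fw$yhat_a, fw$yhat_t, fw$mu, fw$sigma,
                           config = embedder$config)
  )
}

#' Tidy the training log of an embedder
#'
#' @param x A `linkbin_embedder`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `l_a`, `l_t`, `l_kl`,
#'   `total`, `val_total`.
#' @method tidy linkbin_embedder
#' @export
tidy.linkbin_embedder <- function(x, ...) x$log

#' One-row summary of a trained embedder
#'
#' @param x A `linkbin_embedder`.
#' @param ... Unused.
#' @return Tibble with `n_epochs`, `best_epoch`, `val_loss`, `latent_dim`,
#'   `n_train`, `n_val`, `early_stopped`.
#' @method glance linkbin_embedder
#' @export
glance.linkbin_embedder <- function(x, ...) {
  tibble(
    n_epochs = nrow(x$log), best_epoch = x$best_epoch, val_loss = x$val_loss,
    latent_dim = x$config$latent_dim, n_train = x$n_train, n_val = x$n_val,
    early_stopped = nrow(x$log) < x$config$max_epochs
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot embedder training curves
#'
#' @param object A `linkbin_embedder`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss by epoch.
#' @method autoplot linkbin_embedder
#' @export
autoplot.linkbin_embedder <- function(object, ...) {
  df <- object$log |>
    dplyr::select("epoch", training = "total", validation = "val_total") |>
    tidyr::pivot_longer(-"epoch", names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "weighted loss", colour = NULL) +
    ggplot2::theme_minimal()
}
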