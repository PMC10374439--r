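## Convolutional sequence-to-activity regression: the on-target (30-nt
## context + expression-system embedding) and off-target (spacer/target
## 8-channel stack + mismatch features) networks, with MAE loss and Adam.
## Implemented directly on BLAS matrix products (conv as im2col).

#' Network configurations
#'
#' `onTargetConfig()`: 30-nt one-hot input, one convolution layer (256
#' filters, 5 nt, length-preserving zero padding), average pooling, fully
#' connected layers 1500-1500-100, a learned 100-dimensional embedding of
#' the binary expression-system flag multiplied elementwise with the final
#' 100-unit layer, and a linear output.  `offTargetConfig()`: 20-nt spacer
#' and target one-hot encodings stacked as 8 channels, one convolution layer
#' (128 filters, 3 nt for the Sniper1 profile or 5 nt for the Sniper2L
#' profile), average pooling, per-position mismatch codes concatenated after
#' flattening, fully connected layers 1500-1500-1500-100 and a linear
#' output (no expression-system input).  Both use rectified linear
#' activations and dropout 0.3 on the 1500-unit layers.
#'
#' @param conv_filters,conv_width Convolution layer shape (width must be
#'   odd).
#' @param pool_width,pool_stride Average pooling shape.
#' @param fc_sizes Fully connected layer widths; the chain must end at
#'   `embedding_dim` for the on-target model.
#' @param embedding_dim Dimension of the expression-system embedding.
#' @param dropout Dropout rate on the 1500-unit layers (training only).
#' @param variant Off-target filter-width profile: `"sniper1"` (width 3) or
#'   `"sniper2L"` (width 5).
#' @return A config list (class `OnTargetConfig` / `OffTargetConfig`).
#' @export
onTargetConfig <- function(conv_filters = 256L, conv_width = 5L,
                           pool_width = 2L, pool_stride = 2L,
                           fc_sizes = c(1500L, 1500L, 100L),
                           embedding_dim = 100L, dropout = 0.3) {
  if (conv_width %% 2L == 0L) stop("conv_width must be odd", call. = FALSE)
  if (fc_sizes[length(fc_sizes)] != embedding_dim)
    stop("config error: fc chain must end at embedding_dim to permit the ",
         "elementwise product with the system embedding", call. = FALSE)
  structure(list(input_length = 30L, channels = 4L,
                 conv_filters = as.integer(conv_filters),
                 conv_width = as.integer(conv_width),
                 pool_width = as.integer(pool_width),
                 pool_stride = as.integer(pool_stride),
                 fc_sizes = as.integer(fc_sizes),
                 embedding_dim = as.integer(embedding_dim),
                 dropout = dropout),
            class = "OnTargetConfig")
}

#' @rdname onTargetConfig
#' @export
offTargetConfig <- function(variant = c("sniper1", "sniper2L"),
                            conv_filters = 128L, conv_width = NULL,
                            pool_width = 2L, pool_stride = 2L,
                            fc_sizes = c(1500L, 1500L, 1500L, 100L),
                            dropout = 0.3) {
  variant <- match.arg(variant)
  if (is.null(conv_width))
    conv_width <- if (variant == "sniper1") 3L else 5L
  if (!conv_width %in% c(3L, 5L))
    stop("conv_width must be 3 or 5 (variant profile)", call. = FALSE)
  structure(list(input_length = 20L, channels = 8L, variant = variant,
                 conv_filters = as.integer(conv_filters),
                 conv_width = as.integer(conv_width),
                 pool_width = as.integer(pool_width),
                 pool_stride = as.integer(pool_stride),
                 fc_sizes = as.integer(fc_sizes),
                 feature_dim = 20L, dropout = dropout),
            class = "OffTargetConfig")
}

## ---- encodings ---------------------------------------------------------

#' One-hot encode 30-nt target contexts
#'
#' Case-insensitive; each context column carries exactly one 1 across the
#' four base rows.  The expression system is encoded as a binary flag:
#' 0 for (G/g)N19 (U6-driven), 1 for tRNA-N20.
#'
#' @param context Character vector of 30-nt DNA contexts.
#' @param expression_system Character vector (recycled) over
#'   `"gN19"`, `"GN19"`, `"tRNA_N20"`.
#' @return List with `onehot` (array n x 4 x 30, base dimension ordered
#'   ACGT) and `system` (integer 0/1).
#' @export
encodeOnTarget <- function(context, expression_system = "gN19") {
  context <- toupper(context)
  .check_len(context, 30L, "context")
  .check_alphabet(context, .DNA, "context")
  expression_system <- rep_len(expression_system, length(context))
  stopifnot(all(expression_system %in% .EXPR_SYSTEMS))
  n <- length(context)
  cm <- .char_matrix(context)
  oh <- array(0, c(n, 4L, 30L), dimnames = list(NULL, .DNA, NULL))
  idx <- cbind(rep(seq_len(n), 30L), match(as.vector(cm), .DNA),
               rep(seq_len(30L), each = n))
  oh[idx] <- 1
  list(onehot = oh,
       system = as.integer(expression_system == "tRNA_N20"))
}

#' @rdname encodeOnTarget
#' @param encoding An `encodeOnTarget()` result.
#' @return `decodeOnTarget()` returns the context strings.
#' @export
decodeOnTarget <- function(encoding) {
  oh <- encoding$onehot
  n <- dim(oh)[1]
  vapply(seq_len(n), function(i)
    paste(.DNA[apply(oh[i, , , drop = FALSE], 3, which.max)], collapse = ""),
    "")
}

# ordered mismatch code for (spacer base as DNA, protospacer base):
# 0 = match, otherwise 1..12 indexing the ordered substitution
.mismatch_code <- function(sdna, pr) {
  si <- match(sdna, .DNA)
  pi <- match(pr, .DNA)
  ifelse(si == pi, 0L, (si - 1L) * 3L + pi - (pi > si))
}

#' Encode a spacer / mismatched-target pair for the off-target network
#'
#' Channels 1-4 hold the one-hot spacer (U read as T), channels 5-8 the
#' one-hot target, both 5' to 3'.  The mismatch feature vector has one entry
#' per PAM-anchored position: 0 where spacer and target match, otherwise an
#' integer code 1-12 identifying the ordered substitution.  A matched pair
#' yields an all-zero vector.
#'
#' @param spacer Character vector of 20-nt RNA spacers.
#' @param target Character vector of 20-nt DNA protospacers.
#' @return List with `onehot` (array n x 8 x 20) and `features`
#'   (matrix n x 20, columns = PAM-anchored positions 1..20).
#' @export
encodeOffTarget <- function(spacer, target) {
  spacer <- toupper(spacer)
  target <- toupper(target)
  .check_len(spacer, 20L, "spacer")
  .check_len(target, 20L, "target")
  .check_alphabet(spacer, c(.DNA, "U"), "spacer")
  .check_alphabet(target, .DNA, "target")
  if (length(spacer) != length(target))
    stop("spacer and target must have equal length", call. = FALSE)
  n <- length(spacer)
  sm <- .char_matrix(chartr("U", "T", spacer))
  tm <- .char_matrix(target)
  oh <- array(0, c(n, 8L, 20L))
  i <- rep(seq_len(n), 20L)
  j <- rep(seq_len(20L), each = n)
  oh[cbind(i, match(as.vector(sm), .DNA), j)] <- 1
  oh[cbind(i, match(as.vector(tm), .DNA) + 4L, j)] <- 1
  code5 <- matrix(.mismatch_code(as.vector(sm), as.vector(tm)), n, 20L)
  features <- code5[, 20L:1L, drop = FALSE] # column p = PAM-anchored pos p
  colnames(features) <- paste0("pos", seq_len(20L))
  list(onehot = oh, features = features)
}

## ---- model object ------------------------------------------------------

#' DeepSniperModel: a sequence-to-activity regression network
#'
#' Holds the architecture configuration, the weight matrices, the Adam
#' optimizer state and the training history.  Build with [buildModel()],
#' fit with [trainModel()], score with `predict()`.
#'
#' @slot type `"on"` or `"off"`.
#' @slot config An [onTargetConfig()] / [offTargetConfig()].
#' @slot weights Named list of weight matrices/vectors.
#' @slot opt Adam optimizer state.
#' @slot center,scale Label standardization applied during training.
#' @slot history Per-epoch loss history.
#' @export
setClass("DeepSniperModel",
         representation(type = "character", config = "ANY",
                        weights = "list", opt = "list",
                        center = "numeric", scale = "numeric",
                        history = "data.frame"))

setMethod("show", "DeepSniperModel", function(object) {
  cat(sprintf("DeepSniperModel (%s-target): %d parameters\n", object@type,
              paramCount(object)))
  cfg <- object@config
  cat(sprintf("  conv %d x %d nt | pool %d/%d | fc %s%s\n",
              cfg$conv_filters, cfg$conv_width, cfg$pool_width,
              cfg$pool_stride, paste(cfg$fc_sizes, collapse = "-"),
              if (object@type == "on") " | system embedding" else ""))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final train MAE %.3f\n",
                nrow(object@history),
                object@history$train_mae[nrow(object@history)]))
  else cat("  untrained\n")
})

.he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build a network from a configuration
#'
#' Weight initialization is He-normal and deterministic given `seed`; the
#' parameter count is a pure function of the configuration.  The
#' expression-system embedding starts at all-ones so the elementwise product
#' is initially the identity.
#'
#' @param config An [onTargetConfig()] or [offTargetConfig()].
#' @param seed Integer seed for initialization.
#' @return A [DeepSniperModel-class].
#' @export
buildModel <- function(config, seed = 1L) {
  type <- if (inherits(config, "OnTargetConfig")) "on"
          else if (inherits(config, "OffTargetConfig")) "off"
          else stop("config must be an onTargetConfig() or offTargetConfig()",
                    call. = FALSE)
  L <- config$input_length
  P <- (L - config$pool_width) %/% config$pool_stride + 1L
  flat_dim <- P * config$conv_filters
  in_dims <- c(flat_dim + if (type == "off") config$feature_dim else 0L,
               config$fc_sizes[-length(config$fc_sizes)])
  with_seed(seed, {
    w <- list(wc = .he_init(config$channels * config$conv_width,
                            config$conv_filters,
                            config$channels * config$conv_width),
              bc = numeric(config$conv_filters))
    for (l in seq_along(config$fc_sizes)) {
      w[[paste0("w", l)]] <- .he_init(in_dims[l], config$fc_sizes[l],
                                      in_dims[l])
      w[[paste0("b", l)]] <- numeric(config$fc_sizes[l])
    }
    if (type == "on")
      w$emb <- matrix(1, 2L, config$embedding_dim)
    last <- config$fc_sizes[length(config$fc_sizes)]
    w$wout <- .he_init(last, 1L, last)
    w$bout <- 0
    new("DeepSniperModel", type = type, config = config, weights = w,
        opt = list(), center = 0, scale = 1,
        history = data.frame(epoch = integer(0), train_mae = numeric(0),
                             val_mae = numeric(0)))
  })
}

#' Number of trainable parameters
#' @param model A [DeepSniperModel-class].
#' @export
paramCount <- function(model) {
  sum(vapply(model@weights, length, 0L))
}

## ---- forward / backward ------------------------------------------------

# im2col for 1-D convolution with length-preserving zero padding.
# X: array n x C x L -> matrix (n*L) x (C*cw), row index (pos-1)*n + i.
.im2col <- function(X, cw) {
  n <- dim(X)[1]; C <- dim(X)[2]; L <- dim(X)[3]
  pad <- (cw - 1L) %/% 2L
  Xp <- array(0, c(n, C, L + 2L * pad))
  Xp[, , pad + seq_len(L)] <- X
  cols <- vector("list", cw)
  for (k in seq_len(cw)) {
    sl <- aperm(Xp[, , k:(k + L - 1L), drop = FALSE], c(1, 3, 2))
    dim(sl) <- c(n * L, C)
    cols[[k]] <- sl
  }
  do.call(cbind, cols)
}

# forward pass; train = TRUE samples dropout masks (inverted dropout)
.ds_forward <- function(model, enc, train = FALSE) {
  cfg <- model@config
  w <- model@weights
  n <- dim(enc$onehot)[1]
  L <- cfg$input_length
  M <- .im2col(enc$onehot, cfg$conv_width)
  zc <- sweep(M %*% w$wc, 2L, w$bc, "+")
  ac <- pmax(zc, 0)
  # average pooling over positions (rows are position-major blocks of n)
  P <- (L - cfg$pool_width) %/% cfg$pool_stride + 1L
  pooled <- matrix(0, n * P, cfg$conv_filters)
  for (p in seq_len(P)) {
    pos <- (p - 1L) * cfg$pool_stride + seq_len(cfg$pool_width)
    acc <- ac[(pos[1] - 1L) * n + seq_len(n), , drop = FALSE]
    for (q in pos[-1]) acc <- acc + ac[(q - 1L) * n + seq_len(n), , drop = FALSE]
    pooled[(p - 1L) * n + seq_len(n), ] <- acc / cfg$pool_width
  }
  flat <- pooled
  dim(flat) <- c(n, P * cfg$conv_filters)
  h <- if (model@type == "off") cbind(flat, enc$features) else flat
  nl <- length(cfg$fc_sizes)
  Z <- A <- D <- mask <- vector("list", nl)
  x <- h
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(x %*% w[[paste0("w", l)]], 2L, w[[paste0("b", l)]], "+")
    A[[l]] <- pmax(Z[[l]], 0)
    drop_here <- train && cfg$dropout > 0 && l < nl
    if (drop_here) {
      mask[[l]] <- matrix(runif(length(A[[l]])) >= cfg$dropout,
                          nrow(A[[l]]), ncol(A[[l]])) / (1 - cfg$dropout)
      D[[l]] <- A[[l]] * mask[[l]]
    } else D[[l]] <- A[[l]]
    x <- D[[l]]
  }
  if (model@type == "on") {
    e <- w$emb[enc$system + 1L, , drop = FALSE]
    G <- x * e
  } else {
    e <- NULL
    G <- x
  }
  y <- as.numeric(G %*% w$wout + w$bout)
  list(y = y, M = M, zc = zc, ac = ac, flat_in = h, Z = Z, D = D,
       mask = mask, G = G, e = e, n = n, P = P)
}

.ds_backward <- function(model, enc, cache, dy) {
  cfg <- model@config
  w <- model@weights
  n <- cache$n
  g <- list()
  dy <- matrix(dy, n, 1)
  g$wout <- crossprod(cache$G, dy)
  g$bout <- sum(dy)
  dG <- tcrossprod(dy, w$wout)
  nl <- length(cfg$fc_sizes)
  if (model@type == "on") {
    dlast <- dG * cache$e
    demb <- dG * cache$D[[nl]]
    g$emb <- matrix(0, 2L, cfg$embedding_dim)
    for (s in unique(enc$system)) {
      sel <- enc$system == s
      g$emb[s + 1L, ] <- colSums(demb[sel, , drop = FALSE])
    }
  } else {
    dlast <- dG
  }
  dX <- dlast
  for (l in rev(seq_len(nl))) {
    if (!is.null(cache$mask[[l]])) dX <- dX * cache$mask[[l]]
    dZ <- dX * (cache$Z[[l]] > 0)
    below <- if (l == 1L) cache$flat_in else cache$D[[l - 1L]]
    g[[paste0("w", l)]] <- crossprod(below, dZ)
    g[[paste0("b", l)]] <- colSums(dZ)
    dX <- tcrossprod(dZ, w[[paste0("w", l)]])
  }
  # dX is gradient w.r.t. the fc input: strip mismatch features (off model)
  flat_dim <- cache$P * cfg$conv_filters
  dflat <- dX[, seq_len(flat_dim), drop = FALSE]
  dpool <- dflat
  dim(dpool) <- c(n * cache$P, cfg$conv_filters)
  dac <- matrix(0, nrow(cache$ac), cfg$conv_filters)
  for (p in seq_len(cache$P)) {
    pos <- (p - 1L) * cfg$pool_stride + seq_len(cfg$pool_width)
    contrib <- dpool[(p - 1L) * n + seq_len(n), , drop = FALSE] /
      cfg$pool_width
    for (q in pos) {
      rows <- (q - 1L) * n + seq_len(n)
      dac[rows, ] <- dac[rows, ] + contrib
    }
  }
  dzc <- dac * (cache$zc > 0)
  g$wc <- crossprod(cache$M, dzc)
  g$bc <- colSums(dzc)
  g
}

# One Adam step over all parameter tensors.  w and the m/v state are
# updated in place (they are private copies owned by trainModel).
.adam_step <- function(w, g, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.null(opt$t)) {
    opt$t <- 0L
    opt$m <- lapply(w, function(x) x * 0)
    opt$v <- lapply(w, function(x) x * 0)
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(g))
    .adam_update_inplace(w[[nm]], opt$m[[nm]], opt$v[[nm]], g[[nm]],
                         lr, beta1, beta2, eps, bc1, bc2)
  list(w = w, opt = opt)
}

#' Subset an encoding by item index
#'
#' Selects items from an [encodeOnTarget()] / [encodeOffTarget()] result
#' (for train/test splits and fold construction).
#'
#' @param enc An encoding list.
#' @param idx Integer index vector.
#' @return The subset encoding.
#' @export
encodingSubset <- function(enc, idx) {
  out <- list(onehot = enc$onehot[idx, , , drop = FALSE])
  if (!is.null(enc$system)) out$system <- enc$system[idx]
  if (!is.null(enc$features))
    out$features <- enc$features[idx, , drop = FALSE]
  out
}

.enc_subset <- encodingSubset

.enc_n <- function(enc) dim(enc$onehot)[1]

#' Train a network
#'
#' Mean-absolute-error loss with an Adam optimizer at learning rate `1e-4`;
#' activity labels are z-standardized internally (predictions are returned
#' on the percent scale).  The per-epoch history records training MAE (the
#' running minibatch average) and validation MAE, both on the percent scale.
#' Reproducible given `seed`; optional early stopping on validation MAE.
#'
#' @param model A [buildModel()] result.
#' @param enc Training encodings ([encodeOnTarget()] /
#'   [encodeOffTarget()]).
#' @param activity Numeric activity labels (percent).
#' @param epochs,batch_size,lr Optimization schedule.
#' @param validation Optional `list(enc = , activity = )` held-out set.
#' @param patience Early-stopping patience in epochs (Inf = never stop).
#' @param seed Integer seed (shuffling, dropout).
#' @param verbose Print per-epoch losses?
#' @return The fitted [DeepSniperModel-class] (history in `history()`).
#' @export
trainModel <- function(model, enc, activity, epochs = 20L, batch_size = 64L,
                       lr = 1e-4, validation = NULL, patience = Inf,
                       seed = 1L, verbose = FALSE) {
  n <- .enc_n(enc)
  if (n == 0L || length(activity) != n)
    stop("training error: empty dataset or label length mismatch",
         call. = FALSE)
  center <- mean(activity)
  scl <- sd(activity)
  if (!is.finite(scl) || scl <= 0) scl <- 1
  yt <- (activity - center) / scl
  # private deep copies: the Adam step updates these tensors in place
  w <- lapply(model@weights, function(x) x + 0)
  opt <- model@opt
  if (!is.null(opt$m)) {
    opt$m <- lapply(opt$m, function(x) x + 0)
    opt$v <- lapply(opt$v, function(x) x + 0)
  }
  hist <- model@history
  best_val <- Inf
  wait <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / batch_size)
      tr_abs <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
        m2 <- model
        m2@weights <- w
        fw <- .ds_forward(m2, .enc_subset(enc, idx), train = TRUE)
        resid <- fw$y - yt[idx]
        tr_abs <- tr_abs + sum(abs(resid))
        dy <- sign(resid) / length(idx)
        g <- .ds_backward(m2, .enc_subset(enc, idx), fw, dy)
        st <- .adam_step(w, g, opt, lr)
        w <- st$w
        opt <- st$opt
      }
      train_mae <- tr_abs / n * scl
      val_mae <- NA_real_
      if (!is.null(validation)) {
        m2 <- model
        m2@weights <- w
        pv <- .ds_predict_std(m2, validation$enc)
        val_mae <- mean(abs(pv * scl + center - validation$activity))
      }
      hist <- rbind(hist, data.frame(epoch = nrow(hist) + 1L,
                                     train_mae = train_mae,
                                     val_mae = val_mae))
      if (verbose)
        message(sprintf("epoch %d: train MAE %.3f val MAE %.3f",
                        nrow(hist), train_mae, val_mae))
      if (!is.null(validation) && is.finite(patience)) {
        if (val_mae < best_val - 1e-9) {
          best_val <- val_mae
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    }
  })
  model@weights <- w
  model@opt <- opt
  model@center <- center
  model@scale <- scl
  model@history <- hist
  model
}

# eval-mode forward in standardized units, batched to bound memory
.ds_predict_std <- function(model, enc, batch = 512L) {
  n <- .enc_n(enc)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    out[idx] <- .ds_forward(model, .enc_subset(enc, idx), train = FALSE)$y
  }
  out
}

#' Predict activities
#'
#' Eval-mode forward pass (dropout off): deterministic and invariant to
#' batch composition.  Scores are returned on the percent activity scale.
#'
#' @param object A fitted [DeepSniperModel-class].
#' @param newdata Encodings from [encodeOnTarget()] / [encodeOffTarget()].
#' @param ... Ignored.
#' @return Numeric vector of predicted activities.
#' @export
setMethod("predict", "DeepSniperModel", function(object, newdata, ...) {
  expect_ch <- object@config$channels
  d <- dim(newdata$onehot)
  if (length(d) != 3L || d[2] != expect_ch || d[3] != object@config$input_length)
    stop(sprintf("shape error: expected n x %d x %d encoding", expect_ch,
                 object@config$input_length), call. = FALSE)
  .ds_predict_std(object, newdata) * object@scale + object@center
})

#' Training history accessor
#' @param model A [DeepSniperModel-class].
#' @return data.frame `epoch`, `train_mae`, `val_mae`.
#' @export
trainingHistory <- function(model) model@history

#' k-fold cross-validation
#'
#' Random, seed-reproducible fold assignment; the folds are disjoint and
#' exhaust the dataset, so pooled predictions cover every item exactly once.
#' Per-fold and pooled MAE, Pearson and Spearman correlations are reported.
#'
#' @param enc Encodings for the full dataset.
#' @param activity Activity labels (percent).
#' @param config Network configuration.
#' @param k Number of folds.
#' @param epochs,batch_size,lr Schedule passed to [trainModel()].
#' @param seed Integer seed (fold assignment, initialization, training).
#' @return List with `fold` (integer assignment per item), `metrics`
#'   (per-fold data.frame), `pooled` (data.frame `index`, `fold`, `truth`,
#'   `pred`) and `pooled_metrics`.
#' @export
crossValidate <- function(enc, activity, config, k = 5L, epochs = 10L,
                          batch_size = 64L, lr = 1e-4, seed = 1L) {
  n <- .enc_n(enc)
  if (k > n) stop("k must not exceed the dataset size", call. = FALSE)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pooled <- data.frame(index = seq_len(n), fold = fold, truth = activity,
                       pred = NA_real_)
  metrics <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- buildModel(config, seed = seed + f)
    model <- trainModel(model, .enc_subset(enc, which(tr)), activity[tr],
                        epochs = epochs, batch_size = batch_size, lr = lr,
                        seed = seed + 100L + f)
    pred <- predict(model, .enc_subset(enc, which(!tr)))
    pooled$pred[!tr] <- pred
    truth <- activity[!tr]
    ok <- length(pred) > 1L && sd(pred) > 0 && sd(truth) > 0
    metrics <- rbind(metrics, data.frame(
      fold = f, n = sum(!tr), mae = mean(abs(pred - truth)),
      pearson = if (ok) cor(pred, truth) else NA_real_,
      spearman = if (ok) cor(pred, truth, method = "spearman")
                 else NA_real_))
  }
  list(fold = fold, metrics = metrics, pooled = pooled,
       pooled_metrics = data.frame(
         mae = mean(abs(pooled$pred - pooled$truth)),
         pearson = cor(pooled$pred, pooled$truth),
         spearman = cor(pooled$pred, pooled$truth, method = "spearman")))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, weights, label standardization
#' and history.
#'
#' @param model A [DeepSniperModel-class].
#' @param file Path.
#' @export
saveModel <- function(model, file) {
  saveRDS(list(type = model@type, config = model@config,
               weights = model@weights, center = model@center,
               scale = model@scale, history = model@history), file)
  invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
  x <- readRDS(file)
  new("DeepSniperModel", type = x$type, config = x$config,
      weights = x$weights, opt = list(), center = x$center,
      scale = x$scale, history = x$history)
}
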