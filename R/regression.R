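# Leaf nitrogen content prediction from sensitive vegetation indices:
# feature assembly across pixel classes, seeded train/test splitting, and
# four regression methods (MLR, PCR, PLSR, SVMR) with internal
# cross-validated hyperparameter selection.

#' Combine per-class VI tables into a feature matrix
#'
#' Joins the sensitive (class, index) columns across classes by sample_id,
#' drops samples with any missing cell, and standardises each column to mean
#' 0, SD 1. \code{mode = "random_subset"} takes a seeded sample of \code{k}
#' of those columns (the "mixed at random" model-building variant).
#'
#' @param viTables named list of [buildViTable()] tables, names = class
#'   labels.
#' @param sensitive named list (per class) of index names, as returned by
#'   [selectSensitive()]; classes absent from \code{viTables} are ignored.
#' @param mode "concat" (default) or "random_subset".
#' @param k number of columns for random_subset.
#' @param seed integer seed for the subset draw.
#' @return list of class "FeatureMatrix": \code{x} (numeric matrix, rownames =
#'   sample_id, colnames = "class.index"), \code{y} (LNC vector), and
#'   \code{scaling} (per-column center/scale).
#' @export
combineFeatures <- function(viTables, sensitive,
                            mode = c("concat", "random_subset"),
                            k = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(names(viTables)) || any(!nzchar(names(viTables))))
    stop("viTables must be a named list (names = class labels)")
  cols <- list(); ids <- NULL; lncBy <- list()
  for (cls in names(viTables)) {
    tab <- viTables[[cls]]
    idx <- sensitive[[cls]]
    if (is.null(idx)) next
    idx <- intersect(idx, names(tab))
    sub <- tab[, c("sample_id", idx), drop = FALSE]
    names(sub)[-1] <- paste(cls, idx, sep = ".")
    cols[[cls]] <- sub
    lncBy[[cls]] <- stats::setNames(tab$lnc, tab$sample_id)
  }
  if (!length(cols)) stop("no sensitive columns selected")
  merged <- Reduce(function(a, b) merge(a, b, by = "sample_id"), cols)
  lnc <- lncBy[[1]][merged$sample_id]
  x <- as.matrix(merged[, -1, drop = FALSE])
  rownames(x) <- merged$sample_id
  complete <- stats::complete.cases(x) & is.finite(lnc)
  if (any(!complete))
    message(sum(!complete), " sample(s) dropped for missing cells")
  x <- x[complete, , drop = FALSE]; lnc <- lnc[complete]
  if (mode == "random_subset") {
    if (is.null(k)) k <- max(1L, ncol(x) %/% 2L)
    set.seed(as.integer(seed))
    x <- x[, sort(sample.int(ncol(x), min(k, ncol(x)))), drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(x = x, y = unname(lnc),
                 scaling = list(center = ctr, scale = scl)),
            class = "FeatureMatrix")
}

#' Seeded train/test split
#'
#' @param n sample count.
#' @param testFraction held-out fraction (default 0.3).
#' @param seed integer seed.
#' @return list(train, test): disjoint, exhaustive index vectors.
#' @export
splitSamples <- function(n, testFraction = 0.3, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  nTest <- max(1L, round(testFraction * n))
  list(train = sort(idx[(nTest + 1L):n]), test = sort(idx[seq_len(nTest)]))
}

#' Prediction metrics
#'
#' \code{r2 = 1 - SS_res/SS_tot} (not clamped: worse-than-mean predictions go
#' negative), \code{rmse = sqrt(mean squared error)},
#' \code{mae = mean absolute error}. RMSE >= MAE always.
#'
#' @param pred,obs numeric vectors of equal length.
#' @return list(r2, rmse, mae).
#' @export
evaluatePredictions <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  err <- pred - obs
  ssTot <- sum((obs - mean(obs))^2)
  list(r2 = 1 - sum(err^2) / ssTot,
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)))
}

# --- NIPALS partial least squares (univariate response) -----------------

# Returns a function(ncomp) -> list(coef, intercept) on the given training
# data (already centered/scaled X, centered y).
.nipalsPls <- function(X, y, maxComp) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  xMeans <- attr(Xc, "scaled:center")
  W <- matrix(0, p, maxComp)   # weights
  P <- matrix(0, p, maxComp)   # X loadings
  Q <- numeric(maxComp)        # y loadings
  Tm <- matrix(0, n, maxComp)  # scores
  Xr <- Xc; yr <- yc
  ncompEff <- 0L
  for (a in seq_len(maxComp)) {
    w <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xr %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pLoad <- drop(crossprod(Xr, t)) / tt
    q <- sum(yr * t) / tt
    Xr <- Xr - tcrossprod(t, pLoad)
    yr <- yr - q * t
    W[, a] <- w; P[, a] <- pLoad; Q[a] <- q; Tm[, a] <- t
    ncompEff <- a
  }
  function(ncomp) {
    a <- min(ncomp, ncompEff)
    if (a == 0L) return(list(coef = rep(0, p), intercept = mean(y)))
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    # coefficients in the original (centered) X space
    R <- Wa %*% solve(crossprod(Pa, Wa))
    beta <- drop(R %*% Q[seq_len(a)])
    list(coef = beta, intercept = mean(y) - sum(beta * xMeans))
  }
}

.cvFolds <- function(n, folds, seed) {
  set.seed(as.integer(seed))
  split(sample.int(n), rep_len(seq_len(folds), n))
}

#' Fit an LNC model and evaluate it on a held-out split
#'
#' Methods: \code{MLR} ordinary least squares on the features as given;
#' \code{PCR} principal components of the standardised features followed by
#' OLS, component count chosen by k-fold CV; \code{PLSR} NIPALS latent
#' variables, components by CV; \code{SVMR} epsilon-insensitive RBF-kernel
#' support vector regression with (cost, gamma, epsilon) chosen by grid CV.
#' Metrics are computed on the held-out test samples only.
#'
#' @param features a [combineFeatures()] result (or list with x, y).
#' @param method one of "MLR", "PCR", "PLSR", "SVMR".
#' @param seed integer; drives the split and the CV folds.
#' @param testFraction held-out fraction (default 0.3).
#' @param folds CV folds for hyperparameter selection (default 5).
#' @param hyper optional list: \code{maxComp} (PCR/PLSR),
#'   \code{cost}, \code{gamma}, \code{epsilon} grids (SVMR).
#' @param split optional precomputed list(train, test) to reuse across
#'   methods.
#' @return list of class "ModelReport": method, hyperparameters, r2, rmse,
#'   mae, split description, seed, and per-sample test predictions.
#' @export
fitPredict <- function(features, method = c("MLR", "PCR", "PLSR", "SVMR"),
                       seed = 1L, testFraction = 0.3, folds = 5L,
                       hyper = list(), split = NULL) {
  method <- match.arg(method)
  x <- features$x; y <- features$y
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in features or target")
  n <- nrow(x)
  if (is.null(split)) split <- splitSamples(n, testFraction, seed)
  tr <- split$train; te <- split$test
  if (length(tr) < 2L * folds)
    stop("too few training samples for ", folds, "-fold CV")
  xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
  xte <- x[te, , drop = FALSE]; yte <- y[te]
  hp <- list()

  predictFactory <- NULL
  if (method == "MLR") {
    if (length(tr) <= ncol(x))
      stop("MLR needs more training rows (", length(tr),
           ") than features (", ncol(x), "); use PCR or PLSR")
    predictFactory <- function(X, Y) {
      df <- data.frame(Y = Y, X)
      fit <- stats::lm(Y ~ ., data = df)
      function(Xnew) unname(stats::predict(fit, data.frame(Xnew)))
    }
  } else if (method %in% c("PCR", "PLSR")) {
    maxComp <- hyper$maxComp %||%
      min(10L, ncol(x), length(tr) - ceiling(length(tr) / folds) - 2L)
    maxComp <- max(1L, maxComp)
    makeFit <- if (method == "PCR") {
      function(X, Y) {
        pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
        function(ncomp) {
          a <- min(ncomp, ncol(pc$rotation))
          sc <- pc$x[, seq_len(a), drop = FALSE]
          cf <- stats::lm.fit(cbind(1, sc), Y)$coefficients
          rot <- pc$rotation[, seq_len(a), drop = FALSE]
          beta <- drop(rot %*% cf[-1])
          list(coef = beta, intercept = cf[1] - sum(beta * pc$center))
        }
      }
    } else {
      function(X, Y) .nipalsPls(X, Y, maxComp)
    }
    # choose component count by CV RMSE
    foldIdx <- .cvFolds(length(tr), folds, seed)
    cvErr <- matrix(NA_real_, folds, maxComp)
    for (f in seq_len(folds)) {
      hold <- foldIdx[[f]]
      fitAt <- makeFit(xtr[-hold, , drop = FALSE], ytr[-hold])
      for (a in seq_len(maxComp)) {
        b <- fitAt(a)
        pr <- drop(xtr[hold, , drop = FALSE] %*% b$coef) + b$intercept
        cvErr[f, a] <- sqrt(mean((pr - ytr[hold])^2))
      }
    }
    best <- which.min(colMeans(cvErr))
    hp$ncomp <- best
    predictFactory <- function(X, Y) {
      b <- makeFit(X, Y)(best)
      function(Xnew) drop(Xnew %*% b$coef) + b$intercept
    }
  } else { # SVMR
    grid <- expand.grid(
      cost = hyper$cost %||% c(1, 10, 100),
      gamma = hyper$gamma %||% (c(0.5, 1, 2) / ncol(x)),
      epsilon = hyper$epsilon %||% 0.1)
    foldIdx <- .cvFolds(length(tr), folds, seed)
    cvErr <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      errs <- numeric(folds)
      for (f in seq_len(folds)) {
        hold <- foldIdx[[f]]
        fit <- e1071::svm(xtr[-hold, , drop = FALSE], ytr[-hold],
                          type = "eps-regression", kernel = "radial",
                          cost = grid$cost[gi], gamma = grid$gamma[gi],
                          epsilon = grid$epsilon[gi], scale = FALSE)
        pr <- stats::predict(fit, xtr[hold, , drop = FALSE])
        errs[f] <- sqrt(mean((pr - ytr[hold])^2))
      }
      cvErr[gi] <- mean(errs)
    }
    best <- grid[which.min(cvErr), ]
    hp <- as.list(best)
    predictFactory <- function(X, Y) {
      fit <- e1071::svm(X, Y, type = "eps-regression", kernel = "radial",
                        cost = best$cost, gamma = best$gamma,
                        epsilon = best$epsilon, scale = FALSE)
      function(Xnew) unname(stats::predict(fit, Xnew))
    }
  }

  predictor <- predictFactory(xtr, ytr)
  pred <- predictor(xte)
  m <- evaluatePredictions(pred, yte)
  structure(list(
    method = method, hyperparameters = hp,
    r2 = m$r2, rmse = m$rmse, mae = m$mae,
    split = sprintf("%d train / %d test (fraction %.2f)",
                    length(tr), length(te), testFraction),
    seed = seed,
    predictions = data.frame(
      sample_id = rownames(x)[te] %||% as.character(te),
      observed = yte, predicted = pred, stringsAsFactors = FALSE)
  ), class = "ModelReport")
}

#' @export
print.ModelReport <- function(x, ...) {
  cat(sprintf("ModelReport [%s]: R2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
              x$method, x$r2, x$rmse, x$mae))
  cat("  split:", x$split, " seed:", x$seed, "\n")
  if (length(x$hyperparameters))
    cat("  hyperparameters:",
        paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}
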