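# Correlation screening of vegetation indices against leaf nitrogen content,
# standard-error comparison across pretreatments, one-way ANOVA with compact
# letter displays, and sensitive-index selection.

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation coefficient; the two-sided p-value comes from
#' the t transform \code{t = r sqrt((n-2)/(1-r^2))} with n-2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, nonconstant.
#' @return list(r, p, n).
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

.stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' Correlate every index against LNC across a set of VI tables
#'
#' @param viTables list of tables from [buildViTable()] (each carries
#'   \code{classLabel} and \code{pretreat} attributes).
#' @return Long-format data.frame (class, method, index, r, p, stars, n),
#'   ordered by decreasing |r|. Missing cells are dropped pairwise per index;
#'   n is reported per row. Indices with fewer than 3 complete pairs or zero
#'   variance are skipped.
#' @export
correlateViLnc <- function(viTables) {
  if (is.data.frame(viTables)) viTables <- list(viTables)
  rows <- list()
  for (tab in viTables) {
    cls <- attr(tab, "classLabel") %||% "all"
    mth <- attr(tab, "pretreat") %||% "OS"
    idx <- setdiff(names(tab), c("sample_id", "lnc"))
    for (nm in idx) {
      v <- tab[[nm]]; lnc <- tab$lnc
      ok <- is.finite(v) & is.finite(lnc)
      if (sum(ok) < 3L || stats::sd(v[ok]) == 0) next
      pr <- pearsonR(v[ok], lnc[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, method = mth, index = nm,
        r = pr$r, p = pr$p, stars = .stars(pr$p), n = pr$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-index standard error across samples
#'
#' SD/sqrt(n) of each index column, the spread statistic used to flag
#' environment-susceptible indices (GRVI, RVI, MACI, GMI, MTCI show the
#' largest drops after smoothing).
#'
#' @param viTable a table from [buildViTable()].
#' @return Named numeric vector of standard errors.
#' @export
viStandardError <- function(viTable) {
  idx <- setdiff(names(viTable), c("sample_id", "lnc"))
  vapply(idx, function(nm) {
    v <- viTable[[nm]]; v <- v[is.finite(v)]
    stats::sd(v) / sqrt(length(v))
  }, numeric(1))
}

# Compact letter display from a symmetric p-value matrix: maximal cliques of
# the non-significance graph get letters, assigned in descending order of the
# clique's best group mean, so the group with the highest mean carries "a".
.letterDisplay <- function(pmat, means, alpha = 0.05) {
  g <- names(means)
  adj <- pmat >= alpha
  diag(adj) <- TRUE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  cl <- igraph::max_cliques(gr)
  cliques <- lapply(cl, function(c) g[as.integer(c)])
  ord <- order(-vapply(cliques, function(cc) max(means[cc]), numeric(1)))
  cliques <- cliques[ord]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(cliques)) {
    L <- letters[(i - 1L) %% 26L + 1L]
    for (m in cliques[[i]])
      letters_out[m] <- paste0(letters_out[m], L)
  }
  # order letters within each group alphabetically
  vapply(letters_out, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = ""), character(1))
}

#' One-way ANOVA with compact letter display
#'
#' Fits a one-way ANOVA of \code{values ~ group}, runs Tukey HSD pairwise
#' comparisons, and encodes them as lowercase letters: groups sharing a
#' letter are not significantly different at \code{alpha}. Letters are
#' assigned in descending-mean order ("a" = highest mean). This is the layout
#' of the per-pretreatment and per-class significance tables.
#'
#' @param values numeric vector.
#' @param group factor/character of the same length (>= 2 groups, >= 2 values
#'   each).
#' @param alpha significance level (default 0.05).
#' @return data.frame (group, mean, letters), sorted by decreasing mean.
#' @export
anovaLetters <- function(values, group, alpha = 0.05) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  cnt <- table(group)
  if (any(cnt < 2L))
    stop("empty or singleton group(s): ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  df <- data.frame(v = values, g = group)
  fit <- stats::aov(v ~ g, data = df)
  means <- tapply(df$v, df$g, mean)
  if (stats::sd(values) == 0 ||
      stats::anova(fit)[["Mean Sq"]][2] < .Machine$double.eps) {
    # no residual variance: identical groups share a letter iff equal means
    pmat <- outer(means, means, function(a, b)
      ifelse(abs(a - b) < 1e-12, 1, 0))
  } else {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    pmat <- matrix(1, nlevels(group), nlevels(group),
                   dimnames = list(levels(group), levels(group)))
    for (cmp in rownames(tk)) {
      pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[cmp, "p adj"]
    }
  }
  lets <- .letterDisplay(pmat, means, alpha = alpha)
  out <- data.frame(group = names(means), mean = as.numeric(means),
                    letters = lets[names(means)], stringsAsFactors = FALSE)
  out <- out[order(-out$mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select sensitive indices from a correlation report
#'
#' An index is sensitive for a class when its correlation with LNC is both
#' significant (p < alpha) and of sufficient magnitude (|r| >= minAbsR);
#' defaults alpha = 0.05, minAbsR = 0.2.
#'
#' @param report data.frame from [correlateViLnc()].
#' @param alpha significance threshold.
#' @param minAbsR minimum |r|.
#' @return Named list (one element per class) of retained index name vectors,
#'   with a \code{counts} attribute.
#' @export
selectSensitive <- function(report, alpha = 0.05, minAbsR = 0.2) {
  keep <- report[report$p < alpha & abs(report$r) >= minAbsR, , drop = FALSE]
  out <- lapply(split(keep$index, keep$class), unique)
  # preserve class order of first appearance in the report
  out <- out[intersect(unique(report$class), names(out))]
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}
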