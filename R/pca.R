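# Multi-sample intensity matrix assembly and NIPALS principal component
# analysis with a work/prediction-set protocol: log10(1+x) transform,
# unit-variance scaling, iterative component extraction, projection of
# held-out samples and row-wise cross-validated Q2.

#' Assemble a samples x formulas intensity matrix from assignment tables
#'
#' Formulas are matched across samples by exact elemental identity; the
#' intensity of the primary assignment is used and a formula absent from a
#' sample contributes 0. All-zero columns are removed.
#'
#' @param tables list of `assignment_table` objects (>= 2, distinct
#'   `sample_id`s)
#' @param class_labels optional named vector sample_id -> class label
#' @return object of class `intensity_matrix`: numeric matrix samples x
#'   formulas with `class_labels` attribute
#' @export
assemble_matrix <- function(tables, class_labels = NULL) {
  stopifnot(length(tables) >= 2)
  ids <- vapply(tables, function(t) attr(t, "sample_id"), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  }
  prim <- lapply(tables, primary_assignments)
  all_formulas <- sort(unique(unlist(lapply(prim, `[[`, "formula"))))
  x <- matrix(0, nrow = length(tables), ncol = length(all_formulas),
              dimnames = list(ids, all_formulas))
  for (i in seq_along(prim)) {
    p <- prim[[i]]
    agg <- tapply(p$intensity, p$formula, sum)
    x[i, names(agg)] <- agg
  }
  x <- x[, colSums(x) > 0, drop = FALSE]
  intensity_matrix(x, class_labels)
}

#' Construct an intensity matrix from a plain numeric matrix
#'
#' @param x numeric matrix, samples in rows, formulas in columns (named)
#' @param class_labels optional named vector sample -> class
#' @return an `intensity_matrix`
#' @export
intensity_matrix <- function(x, class_labels = NULL) {
  stopifnot(is.matrix(x), all(x >= 0))
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  if (anyDuplicated(colnames(x))) stop("duplicate formulas in column index")
  x <- x[, colSums(x) > 0, drop = FALSE]
  structure(x, class_labels = class_labels,
            class = c("intensity_matrix", "matrix", "array"))
}

#' Log-transform and unit-variance scale an intensity matrix
#'
#' Applies `log10(1 + x)` elementwise, then centers each column and divides
#' by its standard deviation. Columns with zero variance are dropped and
#' recorded so that the identical transform can be replayed on new samples.
#'
#' @param m an `intensity_matrix` or plain non-negative matrix
#' @return list with `x` (transformed matrix), `record` (list:
#'   `column_means`, `column_scales`, `kept_columns`, `dropped_columns`,
#'   `log_applied`, `uv_applied`)
#' @export
preprocess <- function(m) {
  x <- log10(1 + unclass(m))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  record <- list(column_means = mu[keep], column_scales = sdv[keep],
                 kept_columns = colnames(x)[keep],
                 dropped_columns = colnames(x)[!keep],
                 log_applied = TRUE, uv_applied = TRUE)
  x <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sdv[keep], "/")
  list(x = x, record = record)
}

apply_preprocessing <- function(raw, record) {
  raw <- unclass(raw)
  miss <- setdiff(record$kept_columns, colnames(raw))
  if (length(miss) > 0) {
    add <- matrix(0, nrow(raw), length(miss),
                  dimnames = list(rownames(raw), miss))
    raw <- cbind(raw, add)
  }
  x <- log10(1 + raw[, record$kept_columns, drop = FALSE])
  sweep(sweep(x, 2, record$column_means, "-"), 2, record$column_scales, "/")
}

# NIPALS extraction of one component from a residual matrix.
nipals_component <- function(e, tol = 1e-9, max_iter = 5000) {
  t_vec <- e[, which.max(apply(e, 2, stats::var))]
  for (iter in seq_len(max_iter)) {
    p <- crossprod(e, t_vec) / sum(t_vec^2)
    p <- p / sqrt(sum(p^2))
    t_new <- e %*% p
    if (sum((t_new - t_vec)^2) / max(sum(t_new^2), 1e-300) < tol) {
      return(list(scores = as.numeric(t_new), loadings = as.numeric(p),
                  iterations = iter))
    }
    t_vec <- t_new
  }
  NULL
}

#' Fit a principal component model by NIPALS
#'
#' Components are extracted iteratively from the preprocessed matrix; each
#' component's R2X is its explained sum of squares over the total sum of
#' squares. The sign of each component is fixed by making its largest-
#' magnitude loading positive.
#'
#' @param m an `intensity_matrix` (preprocessed internally) or the `x`
#'   element of a [preprocess()] result together with `record`
#' @param n_components number of components (<= min(samples - 1, formulas))
#' @param record preprocessing record when `m` is already preprocessed;
#'   leave `NULL` to have [preprocess()] applied
#' @return object of class `som_pca`: list with `scores`,
#'   `loadings`, `r2x_per_component`, `r2x_cum`, `preprocessing`,
#'   `n_components`
#' @export
fit_pca <- function(m, n_components = 2, record = NULL) {
  if (is.null(record)) {
    pre <- preprocess(m)
    x <- pre$x
    record <- pre$record
  } else {
    x <- unclass(m)
  }
  n_max <- min(nrow(x) - 1L, ncol(x))
  if (n_components > n_max) {
    stop("n_components must be <= min(samples - 1, formulas) = ", n_max)
  }
  tss <- sum(x^2)
  e <- x
  scores <- matrix(0, nrow(x), n_components,
                   dimnames = list(rownames(x),
                                   paste0("PC", seq_len(n_components))))
  loadings <- matrix(0, ncol(x), n_components,
                     dimnames = list(colnames(x),
                                     paste0("PC", seq_len(n_components))))
  r2x <- numeric(n_components)
  for (k in seq_len(n_components)) {
    comp <- nipals_component(e)
    if (is.null(comp)) stop("NIPALS failed to converge for component ", k)
    p <- comp$loadings
    t_vec <- comp$scores
    # orientation convention: largest-|loading| entry positive
    s <- sign(p[which.max(abs(p))])
    if (s < 0) { p <- -p; t_vec <- -t_vec }
    scores[, k] <- t_vec
    loadings[, k] <- p
    e <- e - tcrossprod(t_vec, p)
    r2x[k] <- sum(t_vec^2) / tss
  }
  structure(list(scores = scores, loadings = loadings,
                 r2x_per_component = r2x, r2x_cum = cumsum(r2x),
                 preprocessing = record, n_components = n_components,
                 total_ss = tss),
            class = "som_pca")
}

#' @export
print.som_pca <- function(x, ...) {
  cat(sprintf("NIPALS PCA: %d samples, %d formulas, %d components\n",
              nrow(x$scores), nrow(x$loadings), x$n_components))
  cat(sprintf("  R2X per component: %s\n",
              paste(sprintf("%.3f", x$r2x_per_component), collapse = ", ")))
  cat(sprintf("  R2X(cum) = %.3f\n", x$r2x_cum[x$n_components]))
  invisible(x)
}

#' @export
summary.som_pca <- function(object, ...) {
  print(object)
  tab <- data.frame(component = seq_len(object$n_components),
                    r2x = object$r2x_per_component,
                    r2x_cum = object$r2x_cum)
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' Project new samples into a fitted PCA model
#'
#' Applies the stored log/center/scale preprocessing (missing formulas are
#' treated as zero intensity before preprocessing) and projects onto the
#' loadings. Training rows project onto their own fitted scores.
#'
#' @param object a `som_pca`
#' @param newdata numeric matrix of raw intensities, samples in rows,
#'   formula-named columns
#' @param ... unused
#' @return scores matrix (samples x components)
#' @export
predict.som_pca <- function(object, newdata, ...) {
  x <- apply_preprocessing(newdata, object$preprocessing)
  x %*% object$loadings
}

#' Alias for projecting samples into a PCA model
#' @inheritParams predict.som_pca
#' @param model a `som_pca`
#' @param newdata raw intensity rows
#' @return scores matrix
#' @export
project <- function(model, newdata) predict(model, newdata)

#' @export
plot.som_pca <- function(x, components = c(1, 2), col = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  if (is.null(col)) col <- "steelblue"
  graphics::plot(s[, 1], s[, 2], col = col, pch = 16,
                 xlab = sprintf("PC%d (R2X = %.2f)", components[1],
                                x$r2x_per_component[components[1]]),
                 ylab = sprintf("PC%d (R2X = %.2f)", components[2],
                                x$r2x_per_component[components[2]]),
                 ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  invisible(x)
}

#' Row-wise cross-validated Q2 of a PCA model
#'
#' Rows are split into contiguous folds (7 by default); per fold, a model
#' is fitted on the retained rows and the left-out rows are predicted from
#' its loadings. Each element of a left-out row is predicted from the
#' row's *other* variables: scores are estimated with the element's own
#' loading row excluded (rank-one downdate of the orthonormal loading
#' basis), so the prediction is honest and structure-free data yields
#' non-positive Q2. `Q2(cum, k) = 1 - PRESS_k / TSS` with PRESS
#' accumulated over folds using the first k components; the per-component
#' value is `1 - PRESS_k / PRESS_(k-1)` (with `PRESS_0 = TSS`).
#'
#' @param x preprocessed matrix (the `x` of [preprocess()]) or an
#'   `intensity_matrix` (preprocessed internally)
#' @param n_components number of components to evaluate
#' @param n_folds number of row folds (>= 2, <= number of rows)
#' @return list with `q2_per_component`, `q2_cum`, `n_folds`, `press`
#' @export
q2_cv <- function(x, n_components = 2, n_folds = 7) {
  if (inherits(x, "intensity_matrix")) x <- preprocess(x)$x
  x <- unclass(x)
  n <- nrow(x)
  n_folds <- min(n_folds, n)
  if (n_folds < 2) stop("q2_cv needs at least 2 folds")
  fold <- sort(rep(seq_len(n_folds), length.out = n))  # contiguous blocks
  tss <- sum(x^2)
  press <- numeric(n_components)
  for (f in seq_len(n_folds)) {
    train <- x[fold != f, , drop = FALSE]
    test <- x[fold == f, , drop = FALSE]
    if (nrow(train) < 2) stop("fold ", f, " leaves fewer than 2 training rows")
    n_max <- min(nrow(train) - 1L, ncol(train))
    k_use <- min(n_components, n_max)
    fit <- fit_pca(train, n_components = k_use, record = list(identity = TRUE))
    for (k in seq_len(n_components)) {
      kk <- min(k, k_use)
      p <- fit$loadings[, seq_len(kk), drop = FALSE]
      press[k] <- press[k] + press_elementwise(test, p)
    }
  }
  press_prev <- c(tss, press[-length(press)])
  press_prev <- pmax(press_prev, .Machine$double.eps)
  list(q2_per_component = 1 - press / press_prev,
       q2_cum = 1 - press / tss,
       n_folds = n_folds, press = press)
}

# Predictive residual sum of squares of held-out rows under loading basis
# p (columns orthonormal). Each element j of a row is predicted with its
# own loading row excluded: t_(-j) = (I - p_j p_j^T)^{-1} (P^T x - p_j x_j)
# by Sherman-Morrison, and x_hat_j = p_j^T t_(-j).
press_elementwise <- function(test, p) {
  k <- ncol(p)
  total <- 0
  pj_norm2 <- rowSums(p^2)
  for (r in seq_len(nrow(test))) {
    x <- test[r, ]
    tp_full <- crossprod(p, x)  # k x 1
    for (j in seq_len(ncol(test))) {
      pj <- p[j, ]
      rhs <- tp_full - pj * x[j]
      denom <- 1 - pj_norm2[j]
      if (denom < 1e-12) next  # variable fully determined by the basis
      t_mj <- rhs + pj * sum(pj * rhs) / denom
      total <- total + (x[j] - sum(pj * t_mj))^2
    }
  }
  total
}

#' Formulas with the strongest loadings on a component
#'
#' @param model a `som_pca`
#' @param component component index
#' @param k how many formulas to return (truncated with a warning when
#'   larger than the formula count)
#' @param sign `"positive"` or `"negative"` end of the component
#' @param descriptors optional descriptor table to join on `formula`
#' @return data frame `formula`, `loading`, ordered by loading magnitude,
#'   joined to descriptors when supplied
#' @export
top_loadings <- function(model, component = 1, k = 20,
                         sign = c("positive", "negative"),
                         descriptors = NULL) {
  sign <- match.arg(sign)
  p <- model$loadings[, component]
  if (k > length(p)) {
    warning("k exceeds formula count; returning all ", length(p), " formulas")
    k <- length(p)
  }
  ord <- if (sign == "positive") order(p, decreasing = TRUE) else order(p)
  sel <- ord[seq_len(k)]
  out <- data.frame(formula = names(p)[sel], loading = p[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(descriptors)) {
    out <- merge(out, descriptors, by = "formula", sort = FALSE)
    out <- out[order(if (sign == "positive") -out$loading else out$loading), ]
    rownames(out) <- NULL
  }
  out
}
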