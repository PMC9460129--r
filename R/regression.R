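# Exhaustive regression over firing-combination features: four model
# families (linear, logarithmic, interaction, polynomial), ordinary least
# squares, leave-one-sample-out scoring, and the frozen published equations.

MODEL_FAMILIES <- c("linear", "logarithmic", "interaction", "polynomial")

#' Construct a regression model specification
#'
#' @param family One of `"linear"`, `"logarithmic"`, `"interaction"`,
#'   `"polynomial"`. Interaction uses exactly two variables (main effects
#'   plus their product, each with its own coefficient); polynomial uses
#'   exactly one variable with powers 1..`degree`.
#' @param vars Character vector of explanatory-variable names.
#' @param degree Polynomial degree (ignored by other families).
#' @param method Optional feature-method tag (`"A"` legacy / `"B"` subarea)
#'   used in selection-grid labels.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family, vars, degree = 3L, method = NA_character_) {
  family <- match.arg(family, MODEL_FAMILIES)
  vars <- as.character(vars)
  stopifnot(length(vars) >= 1L, !anyDuplicated(vars))
  if (family == "interaction" && length(vars) != 2L) {
    stop("interaction models use exactly 2 variables")
  }
  if (family == "polynomial") {
    stopifnot(length(vars) == 1L, degree >= 1L)
  }
  structure(list(family = family, vars = vars, degree = as.integer(degree),
                 method = method),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  extra <- if (x$family == "polynomial") paste0(" (degree ", x$degree, ")") else ""
  cat(sprintf("%s model%s: %s\n", x$family, extra, paste(x$vars, collapse = ", ")))
  invisible(x)
}

spec_label <- function(spec) paste(sort(spec$vars), collapse = "+")

#' Enumerate all model specifications of a family
#'
#' Linear and logarithmic families take every variable subset of size
#' 1..`p_max`; the interaction family every unordered pair (15 specs for
#' six candidates); the polynomial family one spec per variable at degree
#' `a_max`.
#'
#' @param family Model family.
#' @param candidates Candidate variable names (screened features plus the
#'   dynamic friction coefficient).
#' @param p_max Largest subset size for linear/logarithmic (default 5,
#'   leaving at least one residual degree of freedom when fitting on seven
#'   training samples); clamped with a warning if it exceeds the number of
#'   candidates.
#' @param a_max Polynomial degree (default 3).
#' @param method Feature-method tag to stamp on each spec.
#' @return List of [model_spec()] objects in deterministic order.
#' @export
enumerate_specs <- function(family, candidates, p_max = 5L, a_max = 3L,
                            method = NA_character_) {
  family <- match.arg(family, MODEL_FAMILIES)
  stopifnot(length(candidates) >= 1L)
  candidates <- as.character(candidates)
  if (family %in% c("linear", "logarithmic")) {
    if (p_max > length(candidates)) {
      warning("p_max clamped to the number of candidates (", length(candidates), ")")
      p_max <- length(candidates)
    }
    specs <- list()
    for (p in seq_len(p_max)) {
      sets <- utils::combn(candidates, p, simplify = FALSE)
      specs <- c(specs, lapply(sets, function(v) {
        model_spec(family, v, method = method)
      }))
    }
    return(specs)
  }
  if (family == "interaction") {
    if (length(candidates) < 2L) return(list())
    return(lapply(utils::combn(candidates, 2L, simplify = FALSE),
                  function(v) model_spec(family, v, method = method)))
  }
  lapply(candidates, function(v) {
    model_spec("polynomial", v, degree = a_max, method = method)
  })
}

#' Design matrix for a model specification
#'
#' Builds the regressor matrix (intercept column first): raw columns
#' (linear), `log10` of each column (logarithmic), the two mains plus their
#' product (interaction), or powers 1..degree of the single variable
#' (polynomial).
#'
#' @param spec A [model_spec()].
#' @param data Data frame containing the spec's variables (rows =
#'   samples).
#' @return Numeric matrix with attribute `labels`, or `NULL` when the spec
#'   is infeasible on this data (logarithm of a non-positive value) — the
#'   documented skip sentinel, not an error.
#' @export
design_matrix <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  miss <- setdiff(spec$vars, names(data))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  V <- as.matrix(data[spec$vars])
  n <- nrow(V)
  xm <- switch(spec$family,
    linear = list(V, spec$vars),
    logarithmic = {
      if (any(V <= 0)) return(NULL)
      list(log10(V), paste0("log10(", spec$vars, ")"))
    },
    interaction = list(cbind(V, V[, 1L] * V[, 2L]),
                       c(spec$vars, paste(spec$vars, collapse = ":"))),
    polynomial = {
      P <- outer(V[, 1L], seq_len(spec$degree), `^`)
      list(P, paste0(spec$vars, "^", seq_len(spec$degree)))
    })
  X <- cbind(1, xm[[1L]])
  dimnames(X) <- list(rownames(data), c("(Intercept)", xm[[2L]]))
  attr(X, "labels") <- colnames(X)
  X
}

#' Fit a model specification by ordinary least squares
#'
#' @param spec A [model_spec()].
#' @param data Data frame of explanatory variables (rows = samples).
#' @param y Numeric response, one value per row of `data`.
#' @return Object of class `tactile_fit` with coefficients, standardized
#'   coefficients (`beta * sd(x) / sd(y)`), per-coefficient p-values,
#'   R-squared, adjusted R-squared and the model F-test p-value; or `NULL`
#'   when infeasible (fewer rows than coefficients, rank deficiency, or an
#'   infeasible design).
#' @export
fit_model <- function(spec, data, y) {
  stopifnot(length(y) == nrow(data), is.numeric(y))
  X <- design_matrix(spec, data)
  if (is.null(X)) return(NULL)
  if (nrow(X) <= ncol(X)) return(NULL)
  labels <- colnames(X)
  d <- as.data.frame(X[, -1L, drop = FALSE])
  names(d) <- paste0("V", seq_len(ncol(d)))
  fm <- stats::lm(y ~ ., data = d)
  if (fm$rank < ncol(X)) return(NULL)
  # perfect fits are routine on planted noiseless data; summary.lm's
  # "essentially perfect fit" warning is uninformative there
  sm <- suppressWarnings(summary(fm))
  coefs <- stats::setNames(stats::coef(fm), labels)
  sdx <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
  std <- stats::setNames(coefs[-1L] * sdx / stats::sd(y), labels[-1L])
  fstat <- sm$fstatistic
  structure(list(
    spec = spec,
    coefficients = coefs,
    std_coefficients = std,
    coef_p = stats::setNames(sm$coefficients[, 4L], labels),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_p = if (!is.null(fstat)) {
      unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
    } else NA_real_,
    n = nrow(X), lm = fm),
    class = "tactile_fit")
}

#' @export
print.tactile_fit <- function(x, ...) {
  print(x$spec)
  print(round(x$coefficients, 4))
  cat(sprintf("R2 = %.3f, adj R2 = %.3f, model p = %.4g (n = %d)\n",
              x$r_squared, x$adj_r_squared, x$f_p, x$n))
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `tactile_fit`.
#' @param newdata Data frame with the spec's variables.
#' @param ... Unused.
#' @return Numeric predictions, or `NULL` if the design is infeasible on
#'   `newdata`.
#' @export
predict.tactile_fit <- function(object, newdata, ...) {
  X <- design_matrix(object$spec, newdata)
  if (is.null(X)) return(NULL)
  drop(X %*% object$coefficients)
}

#' Leave-one-sample-out error of a model specification
#'
#' For each sample, the model is fitted on the remaining samples and the
#' held-out sample predicted; the reported score is the mean of the squared
#' prediction errors over folds (or the root of that mean with
#' `metric = "rmse"`).
#'
#' @param spec A [model_spec()].
#' @param data Per-sample explanatory variables (one row per sample,
#'   typically repetition means), at least 3 rows.
#' @param y Response, one value per sample.
#' @param metric `"mse"` (default) or `"rmse"`.
#' @return Object of class `loso_cv` with `fold_errors` (squared errors,
#'   one per held-out sample), `error`, `metric`; or `NULL` when any fold
#'   is infeasible.
#' @export
loso_error <- function(spec, data, y, metric = c("mse", "rmse")) {
  metric <- match.arg(metric)
  n <- nrow(data)
  stopifnot(n >= 3L, length(y) == n)
  ids <- rownames(data)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sq <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_model(spec, data[-i, , drop = FALSE], y[-i])
    if (is.null(fit)) return(NULL)
    pred <- predict(fit, data[i, , drop = FALSE])
    if (is.null(pred)) return(NULL)
    sq[i] <- (pred - y[i])^2
  }
  err <- mean(sq)
  if (metric == "rmse") err <- sqrt(err)
  structure(list(spec = spec, fold_errors = stats::setNames(sq, ids),
                 error = err, metric = metric),
            class = "loso_cv")
}

method_cells <- function(methods) {
  unlist(lapply(methods, function(m) paste0(m, "-", 1:4)))
}

#' Exhaustive model selection over feature methods and families
#'
#' For each target (a per-sample PC score vector) and each cell of the
#' feature-method x model-family grid (`A-1` .. `B-4` when two methods are
#' given), enumerates every specification, scores it by
#' leave-one-sample-out error, and records the cell minimum; the best cell
#' per target is the grid minimum. Ties are broken by fewer estimated
#' parameters, then by the lexicographic variable label, then by cell
#' order.
#'
#' @param features Named list of per-sample feature tables (e.g.
#'   `list(A = legacy_table, B = subarea_table)`), each a data frame with a
#'   `sample_id` column plus candidate columns.
#' @param targets Data frame with `sample_id` plus one numeric column per
#'   target.
#' @param candidates Optional named list (same names as `features`) of
#'   candidate columns per method; default: all feature columns plus
#'   `mu_prime` when present.
#' @param p_max,a_max Enumeration bounds, see [enumerate_specs()].
#' @param metric Cross-validation metric, see [loso_error()].
#' @return Object of class `model_selection`: `grid` (targets x cells
#'   error matrix, `NA` for all-infeasible cells), `best` (per-target data
#'   frame), `details` (per target and cell, the winning spec and its CV
#'   result), `metric`.
#' @export
select_models <- function(features, targets, candidates = NULL,
                          p_max = 5L, a_max = 3L, metric = c("mse", "rmse")) {
  metric <- match.arg(metric)
  stopifnot(is.list(features), length(features) >= 1L,
            !is.null(names(features)), is.data.frame(targets),
            "sample_id" %in% names(targets))
  tnames <- setdiff(names(targets), "sample_id")
  stopifnot(length(tnames) >= 1L)
  methods <- names(features)
  cells <- method_cells(methods)
  grid <- matrix(NA_real_, length(tnames), length(cells),
                 dimnames = list(tnames, cells))
  details <- stats::setNames(vector("list", length(tnames)), tnames)
  for (tn in tnames) details[[tn]] <- stats::setNames(
    vector("list", length(cells)), cells)
  for (m in methods) {
    ft <- features[[m]]
    stopifnot("sample_id" %in% names(ft))
    ord <- match(targets$sample_id, ft$sample_id)
    if (anyNA(ord)) stop("method ", m, ": feature table lacks some target samples")
    ft <- ft[ord, , drop = FALSE]
    rownames(ft) <- ft$sample_id
    cand <- if (!is.null(candidates)) candidates[[m]] else {
      c(feature_columns(ft), intersect("mu_prime", names(ft)))
    }
    for (fi in seq_along(MODEL_FAMILIES)) {
      fam <- MODEL_FAMILIES[fi]
      specs <- enumerate_specs(fam, cand, p_max = min(p_max, length(cand)),
                               a_max = a_max, method = m)
      if (length(specs) == 0L) next
      cell <- paste0(m, "-", fi)
      for (tn in tnames) {
        y <- targets[[tn]]
        cvs <- lapply(specs, loso_error, data = ft, y = y, metric = metric)
        ok <- !vapply(cvs, is.null, logical(1L))
        if (!any(ok)) next
        errs <- vapply(cvs[ok], `[[`, numeric(1L), "error")
        np <- vapply(specs[ok], function(s) {
          switch(s$family, interaction = 4L, polynomial = s$degree + 1L,
                 length(s$vars) + 1L)
        }, integer(1L))
        lab <- vapply(specs[ok], spec_label, character(1L))
        pick <- order(errs, np, lab)[1L]
        grid[tn, cell] <- errs[pick]
        details[[tn]][[cell]] <- list(spec = specs[ok][[pick]],
                                      cv = cvs[ok][[pick]])
      }
    }
  }
  best <- do.call(rbind, lapply(tnames, function(tn) {
    row <- grid[tn, ]
    if (all(is.na(row))) {
      return(data.frame(target = tn, cell = NA_character_,
                        method = NA_character_, family = NA_character_,
                        variables = NA_character_, error = NA_real_))
    }
    j <- which.min(row)  # ties: first cell in fixed order
    sp <- details[[tn]][[j]]$spec
    data.frame(target = tn, cell = names(row)[j], method = sp$method,
               family = sp$family, variables = paste(sp$vars, collapse = "+"),
               error = row[[j]], stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL
  structure(list(grid = grid, best = best, details = details,
                 metric = metric),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Leave-one-sample-out model selection (", x$metric, ")\n", sep = "")
  print(round(x$grid, 4))
  cat("\nBest model per target:\n")
  print(x$best, digits = 4)
  invisible(x)
}

#' Write a selection grid to CSV
#'
#' One row per target, one column per feature-method/family cell.
#'
#' @param selection A [select_models()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(selection, path) {
  stopifnot(inherits(selection, "model_selection"))
  g <- as.data.frame(selection$grid)
  utils::write.csv(cbind(target = rownames(selection$grid), g), path,
                   row.names = FALSE)
  invisible(path)
}

#' Identifiers of the frozen published regression equations
#'
#' @return Character vector `C1PC1`, `C1PC2`, `C2PC1`, `C2PC2`, `C2PC3`
#'   (cluster / principal component).
#' @export
frozen_model_ids <- function() c("C1PC1", "C1PC2", "C2PC1", "C2PC2", "C2PC3")

#' Evaluate a frozen published tactile-estimation equation
#'
#' Evaluates one of the five published best-per-target regression equations
#' with its printed coefficients verbatim (logarithms base 10): a
#' four-variable logarithmic model for cluster 1 PC1, a cubic polynomial in
#' `D_SAIIFAII` (no intercept) for cluster 1 PC2, a two-variable
#' logarithmic model for cluster 2 PC1, a three-variable linear model for
#' cluster 2 PC2, and an interaction model for cluster 2 PC3.
#'
#' @param model_id One of [frozen_model_ids()].
#' @param features Named numeric vector, list or single-row data frame
#'   providing the required features among `D_SAISAIIFAI`, `D_SAIIFAII`,
#'   `D_FAII`, `D_SAISAIIFAII`, `D_ALL` and `mu_prime`. Missing features
#'   raise an error naming them; logarithmic terms require positive
#'   arguments.
#' @return Predicted principal-component score (numeric, vectorized over
#'   feature rows).
#' @examples
#' evaluate_frozen("C2PC1", c(D_SAISAIIFAI = 1, mu_prime = 1))  # -16.88
#' evaluate_frozen("C1PC2", c(D_SAIIFAII = 0))                  # 0
#' @export
evaluate_frozen <- function(model_id, features) {
  model_id <- match.arg(model_id, frozen_model_ids())
  if (is.data.frame(features)) features <- as.list(features)
  get_f <- function(nm) {
    if (is.na(match(nm, names(features)))) {
      stop("missing feature '", nm, "' for model ", model_id)
    }
    as.numeric(features[[nm]])
  }
  lg <- function(x, nm) {
    if (any(x <= 0)) {
      stop("model ", model_id, " needs a positive '", nm, "' (logarithmic term)")
    }
    log10(x)
  }
  switch(model_id,
    C1PC1 = -4136 +
      5.544 * lg(get_f("D_SAISAIIFAI"), "D_SAISAIIFAI") -
      98.20 * lg(get_f("D_SAIIFAII"), "D_SAIIFAII") +
      466.3 * lg(get_f("D_FAII"), "D_FAII") +
      0.9490 * lg(get_f("mu_prime"), "mu_prime"),
    C1PC2 = {
      d <- get_f("D_SAIIFAII")
      1.828 * d - 3.5e-4 * d^2 + 1.69e-8 * d^3
    },
    C2PC1 = -16.88 +
      2.856 * lg(get_f("D_SAISAIIFAI"), "D_SAISAIIFAI") +
      1.114 * lg(get_f("mu_prime"), "mu_prime"),
    C2PC2 = -94.98 +
      4.824e-3 * get_f("D_SAISAIIFAII") -
      4.270e-3 * get_f("D_ALL") +
      8.772e-3 * get_f("D_SAIIFAII"),
    C2PC3 = 4911 -
      2.237 * get_f("D_SAISAIIFAII") -
      0.4273 * get_f("D_SAIIFAII") +
      2.151e-4 * get_f("D_SAISAIIFAI") * get_f("D_SAIIFAII")
  )
}
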