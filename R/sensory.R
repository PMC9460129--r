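# Semantic-differential sensory panels: subject clustering (Ward/Euclidean),
# correlation-matrix PCA with an eigenvalue > 1 retention rule, and
# per-sample mean PC scores used as regression targets.

#' Construct a sensory panel
#'
#' Validates a long-format semantic-differential score table: every
#' (subject, sample, word) cell present exactly once, integer scores on the
#' seven-step unipolar scale 1..7.
#'
#' @param scores Data frame with columns `subject`, `sample`, `word`,
#'   `score`.
#' @return Object of class `sensory_panel` with fields `scores` (long data
#'   frame), `subjects`, `samples`, `words`.
#' @export
sensory_panel <- function(scores) {
  need <- c("subject", "sample", "word", "score")
  stopifnot(is.data.frame(scores), all(need %in% names(scores)))
  s <- scores[need]
  s$subject <- as.character(s$subject)
  s$sample <- as.character(s$sample)
  s$word <- as.character(s$word)
  if (anyNA(s)) stop("panel contains missing values")
  if (any(s$score != round(s$score)) || any(s$score < 1) || any(s$score > 7)) {
    stop("scores must be integers in 1..7")
  }
  tab <- table(s$subject, s$sample, s$word)
  if (any(tab != 1L)) {
    stop("every (subject, sample, word) cell must appear exactly once")
  }
  structure(list(scores = s,
                 subjects = sort(unique(s$subject)),
                 samples = sort(unique(s$sample)),
                 words = sort(unique(s$word))),
            class = "sensory_panel")
}

#' @export
print.sensory_panel <- function(x, ...) {
  cat(sprintf("Sensory panel: %d subjects x %d samples x %d words (scale 1-7)\n",
              length(x$subjects), length(x$samples), length(x$words)))
  invisible(x)
}

#' Read a sensory panel from long-format CSV
#'
#' @param path CSV with columns `subject_id`, `sample_id`, `word`, `score`
#'   (or already `subject`/`sample`).
#' @return A [sensory_panel()].
#' @export
read_panel_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("subject_id" %in% names(d)) names(d)[names(d) == "subject_id"] <- "subject"
  if ("sample_id" %in% names(d)) names(d)[names(d) == "sample_id"] <- "sample"
  sensory_panel(d)
}

# subjects x (sample:word) matrix, columns in deterministic order
panel_subject_matrix <- function(panel) {
  s <- panel$scores
  key <- paste(s$sample, s$word, sep = ":")
  cols <- sort(unique(key))
  m <- matrix(NA_real_, length(panel$subjects), length(cols),
              dimnames = list(panel$subjects, cols))
  m[cbind(match(s$subject, panel$subjects), match(key, cols))] <- s$score
  m
}

# (subject, sample) observations x word matrix for a subject subset
panel_observation_matrix <- function(panel, subjects = NULL) {
  if (is.null(subjects)) subjects <- panel$subjects
  stopifnot(length(subjects) >= 1L, all(subjects %in% panel$subjects))
  s <- panel$scores[panel$scores$subject %in% subjects, ]
  obs <- sort(unique(paste(s$subject, s$sample, sep = ":")))
  m <- matrix(NA_real_, length(obs), length(panel$words),
              dimnames = list(obs, panel$words))
  m[cbind(match(paste(s$subject, s$sample, sep = ":"), obs),
          match(s$word, panel$words))] <- s$score
  m
}

#' Cluster panel subjects (Ward linkage, Euclidean distance)
#'
#' Each subject is represented by their flattened sample-by-word score
#' vector; agglomerative clustering uses Euclidean distances with Ward's
#' minimum-variance criterion (`hclust` method `"ward.D2"`, which operates
#' on unsquared Euclidean distances) and the tree is cut into `k` groups.
#'
#' @param panel A [sensory_panel()].
#' @param k Number of clusters (default 2).
#' @return Object of class `subject_clusters`: `tree` (an `hclust`),
#'   `assignments` (named integer vector over subjects), `k`.
#' @export
cluster_subjects <- function(panel, k = 2L) {
  stopifnot(inherits(panel, "sensory_panel"), k >= 1L)
  if (k > length(panel$subjects)) {
    stop("k = ", k, " exceeds the number of subjects (", length(panel$subjects), ")")
  }
  m <- panel_subject_matrix(panel)
  tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "ward.D2")
  structure(list(tree = tree,
                 assignments = stats::cutree(tree, k = k), k = as.integer(k)),
            class = "subject_clusters")
}

#' @export
print.subject_clusters <- function(x, ...) {
  cat(sprintf("Ward/Euclidean subject clustering, k = %d (sizes: %s)\n",
              x$k, paste(table(x$assignments), collapse = ", ")))
  invisible(x)
}

#' Correlation-matrix PCA of panel scores
#'
#' Rows are (subject, sample) observations, columns are words. Components
#' are extracted from the correlation matrix and retained while their
#' eigenvalue exceeds 1 (Kaiser rule); loadings are eigenvectors scaled by
#' the square root of their eigenvalue, and each component's sign is fixed
#' so its largest-magnitude loading is positive. No rotation is applied.
#'
#' @param panel A [sensory_panel()], or a numeric observation matrix whose
#'   row names `subject:sample` encode the observation (as produced
#'   internally from a panel).
#' @param subjects Optional subject subset (e.g. one cluster).
#' @param min_eigenvalue Retention cutoff (default 1).
#' @return Object of class `panel_pca`: `loadings` (word x PC), all
#'   `eigenvalues`, `contribution` and `cumulative` percentages for the
#'   retained PCs, `scores` data frame (subject, sample, PC1..), `n_words`.
#' @export
run_pca <- function(panel, subjects = NULL, min_eigenvalue = 1) {
  X <- if (inherits(panel, "sensory_panel")) {
    panel_observation_matrix(panel, subjects)
  } else {
    stopifnot(is.matrix(panel), is.numeric(panel))
    panel
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance word column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values > min_eigenvalue)
  if (length(keep) == 0L) {
    stop("no component exceeds the eigenvalue cutoff ", min_eigenvalue)
  }
  V <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  loadings <- sweep(V, 2L, sqrt(lam), `*`)
  # sign convention: largest-|loading| word positive in each PC
  flip <- vapply(seq_along(keep), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, numeric(1L))
  loadings <- sweep(loadings, 2L, flip, `*`)
  V <- sweep(V, 2L, flip, `*`)
  scores <- scale(X) %*% V
  pcs <- paste0("PC", seq_along(keep))
  dimnames(loadings) <- list(colnames(X), pcs)
  colnames(scores) <- pcs
  ids <- do.call(rbind, strsplit(rownames(X), ":", fixed = TRUE))
  sc <- data.frame(subject = ids[, 1L], sample = ids[, 2L],
                   scores, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(loadings = loadings, eigenvalues = e$values,
                 retained = keep,
                 contribution = 100 * lam / ncol(X),
                 cumulative = cumsum(100 * lam / ncol(X)),
                 scores = sc, n_words = ncol(X)),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d of %d components retained (eigenvalue > 1)\n",
              length(x$retained), x$n_words))
  cat("Eigenvalues:", paste(sprintf("%.3f", x$eigenvalues[x$retained]),
                            collapse = ", "),
      sprintf("(cumulative contribution %.1f%%)\n", max(x$cumulative)))
  invisible(x)
}

#' Per-sample mean principal-component scores
#'
#' Averages the (subject, sample) row scores over subjects within each
#' sample; these per-sample means are the objective variables of the
#' tactile-estimation regressions.
#'
#' @param pca A [run_pca()] result.
#' @return Data frame: `sample_id` plus one column per retained PC.
#' @export
sample_pc_scores <- function(pca) {
  stopifnot(inherits(pca, "panel_pca"))
  sc <- pca$scores
  pcs <- grep("^PC", names(sc), value = TRUE)
  agg <- stats::aggregate(sc[pcs], by = list(sample_id = sc$sample), FUN = mean)
  agg[order(agg$sample_id), , drop = FALSE]
}
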