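#' Construct a gene set
#'
#' @param name gene-set name.
#' @param members character vector of feature names (unique, nonempty).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  if (length(members) == 0) abort("gene set must be nonempty")
  if (anyDuplicated(members)) abort("gene-set members must be unique")
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is tab-separated: set name, description, then members.
#'
#' @param path path to a `.gmt` file.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (need name, description, >= 1 member)")
    gene_set(parts[1], unique(parts[-(1:2)]))
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

activity_feature_cols <- function(mat) {
  setdiff(names(mat)[vapply(mat, is.numeric, logical(1))], c("cell"))
}

#' Per-cell gene-set activity score
#'
#' The score of a cell is the mean of the set's member features for that
#' cell; members absent from the matrix are dropped and reported. Group
#' means (e.g. healthy vs metabolically inflexible beta cells) are
#' computed alongside.
#'
#' @param mat an activity/expression tibble: columns `cell`, `group`, and
#'   one numeric column per feature (as from
#'   [simulate_activity_matrix()]).
#' @param set a [gene_set()].
#' @return An object of class `gene_set_score`: per-cell `scores`
#'   tibble (`cell`, `group`, `score`), `group_means`, and the member
#'   bookkeeping.
#' @export
gene_set_score <- function(mat, set) {
  stopifnot(is.data.frame(mat), inherits(set, "gene_set"))
  feats <- activity_feature_cols(mat)
  used <- intersect(set$members, feats)
  dropped <- setdiff(set$members, feats)
  if (length(used) == 0) {
    abort(sprintf("no member of gene set '%s' is present in the matrix", set$name))
  }
  score <- rowMeans(as.matrix(mat[, used, drop = FALSE]))
  scores <- tibble(cell = mat$cell,
                   group = if ("group" %in% names(mat)) mat$group else NA_character_,
                   score = score)
  group_means <- dplyr::summarise(dplyr::group_by(scores, .data$group),
                                  mean_score = mean(.data$score),
                                  n = dplyr::n(), .groups = "drop")
  structure(list(scores = scores, group_means = group_means,
                 set = set$name, members_used = used,
                 members_dropped = dropped),
            class = "gene_set_score")
}

#' @export
print.gene_set_score <- function(x, ...) {
  cat(sprintf("<gene_set_score> set '%s': %d member(s) used, %d dropped\n",
              x$set, length(x$members_used), length(x$members_dropped)))
  print(x$group_means)
  invisible(x)
}

#' @export
tidy.gene_set_score <- function(x, ...) x$scores

#' @export
glance.gene_set_score <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$group_means, names_from = "group",
                             values_from = c("mean_score", "n"))
  dplyr::bind_cols(tibble(set = x$set, n_members = length(x$members_used)), wide)
}

#' Preranked gene-set enrichment
#'
#' Walks the ranking from top to bottom accumulating a running-sum
#' statistic: a set member ("hit") at a feature with score s adds
#' `|s|^weight / sum over hits of |s|^weight`; a non-member subtracts
#' `1 / (N - N_hits)`. The enrichment score (ES) is the signed maximum
#' deviation of the running sum from zero. The null distribution comes
#' from `n_perm` random same-size member sets drawn from the ranked
#' features; NES is the ES divided by the mean |null ES| of matching
#' sign, and p is the one-sided frequency of matching-sign null ES at
#' least as extreme, with the add-one correction.
#'
#' @param ranking a data frame with columns `feature` (no duplicates) and
#'   `score`; it is sorted by decreasing score internally.
#' @param set a [gene_set()]; must be a proper nonempty subset of the
#'   ranked features.
#' @param weight exponent on |score| for hit increments (1 = the
#'   conventional default; 0 = the unweighted Kolmogorov-Smirnov-like
#'   statistic).
#' @param n_perm number of null sets.
#' @param seed integer seed.
#' @return An object of class `enrichment_result`: `es`, `nes`, `p`,
#'   `n_perm`, `seed`, `weight`, plus the running-sum `curve` and the
#'   `null_es` sample.
#' @export
preranked_enrichment <- function(ranking, set, weight = 1, n_perm = 1000,
                                 seed = NULL) {
  stopifnot(is.data.frame(ranking), inherits(set, "gene_set"))
  if (!all(c("feature", "score") %in% names(ranking))) {
    abort("ranking needs 'feature' and 'score' columns")
  }
  if (anyDuplicated(ranking$feature)) abort("ranking has duplicate features")
  ord <- order(ranking$score, decreasing = TRUE)
  feats <- ranking$feature[ord]
  scores <- ranking$score[ord]
  N <- length(feats)
  hits <- which(feats %in% set$members)
  if (length(hits) == 0) abort("no gene-set member is present in the ranking")
  if (length(hits) == N) abort("gene set covers the whole ranking: ES undefined")

  obs <- running_sum_es(hits, scores, weight)
  with_seed(seed, {
    k <- length(hits)
    null_es <- vapply(seq_len(n_perm), function(b) {
      es_from_hits(sort(sample.int(N, k)), scores, weight, N)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same) > 0) obs$es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (length(same) + 1)
    structure(list(es = obs$es, nes = nes, p = p,
                   n_perm = as.integer(n_perm), seed = seed, weight = weight,
                   set = set$name, n_features = N, n_hits = k,
                   curve = obs$curve, null_es = null_es),
              class = "enrichment_result")
  })
}

# ES from sorted hit positions: between hits the running sum falls
# linearly, so its extrema are the values just before and just after
# each hit; the walk ends at zero.
es_from_hits <- function(hits, scores, weight, N, extrema = FALSE) {
  k <- length(hits)
  w <- abs(scores[hits])^weight
  denom <- sum(w)
  inc <- if (denom > 0) w / denom else rep(1 / k, k)
  miss_dec <- 1 / (N - k)
  after <- cumsum(inc) - (hits - seq_len(k)) * miss_dec
  before <- after - inc
  hi <- max(after)
  lo <- min(before)
  es <- if (hi >= -lo) hi else lo
  if (!extrema) return(es)
  list(es = es, before = before, after = after)
}

running_sum_es <- function(hits, scores, weight) {
  N <- length(scores)
  ex <- es_from_hits(hits, scores, weight, N, extrema = TRUE)
  curve <- tibble(
    position = c(0, rep(hits, each = 2) - c(1, 0), N),
    value = c(0, as.numeric(rbind(ex$before, ex$after)), 0))
  list(es = ex$es, curve = curve)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> set '%s' (%d/%d hits, weight %g): ES = %.3f, NES = %.3f, p = %.4g (%d perms)\n",
              x$set, x$n_hits, x$n_features, x$weight, x$es, x$nes, x$p,
              x$n_perm))
  invisible(x)
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(set = x$set, es = x$es, nes = x$nes, p = x$p, weight = x$weight,
         n_hits = x$n_hits, n_features = x$n_features, n_perm = x$n_perm)
}

#' Pearson correlation of regulator activity with a component feature
#'
#' Standard product-moment correlation with the t-distribution two-sided
#' p-value. Constant inputs are a reported error, never a silent `NaN`.
#'
#' @param data optional data frame holding the two columns; when
#'   supplied, `regulator` and `component` are column names.
#' @param regulator,component numeric vectors (or column names when
#'   `data` is given), length >= 3, non-constant.
#' @return A one-row tibble: `r`, `p`, `n`, `df`.
#' @export
regulator_correlation <- function(regulator, component, data = NULL) {
  if (!is.null(data)) {
    regulator <- data[[regulator]]
    component <- data[[component]]
  }
  if (length(regulator) != length(component)) abort("inputs differ in length")
  if (length(regulator) < 3) abort("need at least 3 cells")
  if (sd(regulator) == 0 || sd(component) == 0) {
    abort("correlation undefined: one of the inputs is constant")
  }
  ct <- stats::cor.test(regulator, component, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value,
         n = length(regulator), df = unname(ct$parameter))
}
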