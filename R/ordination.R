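# Beta diversity and stratification: Bray-Curtis distances on normalized
# counts, classical PCoA, silhouette scoring of condition labellings, and
# the four-subset (SHOTGUN / 16S / SHOTGUNex / 16Sex) analysis.

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = sum_g |x_ig - x_jg| / sum_g (x_ig + x_jg)` over a
#' sample x genus matrix of non-negative abundances (typically counts
#' normalized by size factors).
#'
#' @param mat Sample x genus numeric matrix, non-negative, no all-zero row.
#' @return Symmetric sample x sample matrix with zero diagonal and entries
#'   in `[0, 1]`, with attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  zero_rows <- rownames(mat)[rowSums(mat) == 0]
  if (is.null(rownames(mat))) zero_rows <- which(rowSums(mat) == 0)
  if (length(zero_rows))
    stop("all-zero sample row(s): ", paste(zero_rows, collapse = ", "))
  d <- as.matrix(vegan::vegdist(mat, method = "bray"))
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Classical principal coordinate analysis
#'
#' Gower double-centering of `-D^2 / 2` followed by a symmetric
#' eigendecomposition; axes are ordered by decreasing eigenvalue,
#' negative-eigenvalue axes (possible for non-Euclidean dissimilarities
#' such as Bray-Curtis) are dropped and their total magnitude reported, and
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalue, so Euclidean input distances are reproduced exactly.
#'
#' @param dist Symmetric dissimilarity matrix (n >= 3).
#' @return A list: `coordinates` (sample x axis), `eigenvalues` (positive,
#'   non-increasing), `prop_explained` (relative to the positive
#'   eigenvalue total), `negative_inertia` (sum of |negative eigenvalues|).
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3) stop("PCoA needs at least 3 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  tol <- 1e-8 * max(abs(eig))
  pos <- which(eig > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = eig[pos],
       prop_explained = eig[pos] / sum(eig[pos]),
       negative_inertia = sum(abs(eig[eig < 0])))
}

#' Mean silhouette score of a labelling on a distance matrix
#'
#' Per sample, `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' distance to the other members of its own group and `b_i` the smallest
#' mean distance to another group; members of singleton groups score 0.
#' The mean over samples summarizes how well the labelling matches the
#' distance structure (1 = perfectly separated, 0 = random, negative =
#' misassigned).
#'
#' @param dist Symmetric distance matrix.
#' @param labels Group labels, one per sample; at least 2 distinct groups,
#'   each with at least one member.
#' @return A list `mean` and `widths` (per-sample silhouette values).
#' @export
mean_silhouette <- function(dist, labels) {
  d <- as.matrix(dist)
  labels <- as.character(labels)
  if (length(labels) != nrow(d))
    stop("one label per sample required")
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  n <- nrow(d)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { widths[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(groups[groups != labels[i]], function(g)
      mean(d[i, labels == g]), numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  list(mean = mean(widths), widths = widths)
}

# dataset-level exclusivity: a genus is strategy-exclusive iff detected in
# at least one sample of that strategy and in no sample of the other.
strategy_detected <- function(set) {
  det <- list()
  for (s in c("16S", "shotgun")) {
    ids <- set$metadata$sample_id[set$metadata$strategy == s]
    det[[s]] <- unique(unlist(lapply(set$profiles[ids], function(p)
      names(p$counts)), use.names = FALSE))
  }
  det
}

#' Silhouette stratification over strategy-defined genus subsets
#'
#' For each of the four genus subsets -- all genera detected by shotgun
#' (`SHOTGUN`), all detected by 16S (`16S`), and the dataset-level
#' exclusive sets (`SHOTGUNex`: detected by shotgun in at least one sample
#' and by 16S in none; `16Sex`: the reverse) -- the per-strategy count
#' matrix is normalized with median-of-ratios size factors (computed once
#' on the full strategy matrix, so subsetting genera does not change the
#' normalization), restricted to the subset, and scored: Bray-Curtis
#' distances, then the mean silhouette for compartment labels over all
#' samples and for day labels within each compartment. Samples with no
#' reads in a subset are dropped from that subset's scoring (and counted).
#'
#' @param set A [profile_set()], typically quality-filtered.
#' @return Data frame with columns `subset`, `labelling` (`"compartment"`,
#'   `"day:caeca"`, `"day:crop"`), `n_genera`, `n_samples`,
#'   `n_samples_dropped`, `mean_silhouette`. Empty subsets or labellings
#'   with fewer than 2 groups yield `NA` with a warning.
#' @export
stratification_analysis <- function(set) {
  det <- strategy_detected(set)
  subsets <- list(
    SHOTGUN = list(strategy = "shotgun", genera = det$shotgun),
    `16S` = list(strategy = "16S", genera = det$`16S`),
    SHOTGUNex = list(strategy = "shotgun",
                     genera = setdiff(det$shotgun, det$`16S`)),
    `16Sex` = list(strategy = "16S",
                   genera = setdiff(det$`16S`, det$shotgun))
  )
  norm_mats <- list()
  for (s in c("16S", "shotgun")) {
    counts <- profile_matrix(set, s)
    sf <- tryCatch(size_factors(counts),
                   error = function(e)
                     size_factors(counts, pseudo_reference = TRUE))
    norm_mats[[s]] <- t(sweep(counts, 2, sf, "/"))  # samples x genera
  }
  rows <- list()
  for (name in names(subsets)) {
    sub <- subsets[[name]]
    md <- set$metadata[set$metadata$strategy == sub$strategy, ]
    if (!length(sub$genera)) {
      warning("empty genus subset: ", name)
      for (lab in c("compartment", "day:caeca", "day:crop"))
        rows[[length(rows) + 1]] <- data.frame(
          subset = name, labelling = lab, n_genera = 0L, n_samples = 0L,
          n_samples_dropped = 0L, mean_silhouette = NA_real_,
          stringsAsFactors = FALSE)
      next
    }
    mat <- norm_mats[[sub$strategy]][md$sample_id, sub$genera,
                                     drop = FALSE]
    score <- function(sample_ids, labels) {
      m <- mat[sample_ids, , drop = FALSE]
      nonzero <- rowSums(m) > 0
      m <- m[nonzero, , drop = FALSE]
      labels <- labels[nonzero]
      dropped <- sum(!nonzero)
      if (nrow(m) < 3 || length(unique(labels)) < 2)
        return(list(ss = NA_real_, n = nrow(m), dropped = dropped))
      ss <- mean_silhouette(bray_curtis(m), labels)$mean
      list(ss = ss, n = nrow(m), dropped = dropped)
    }
    sc <- score(md$sample_id, md$compartment)
    rows[[length(rows) + 1]] <- data.frame(
      subset = name, labelling = "compartment",
      n_genera = length(sub$genera), n_samples = sc$n,
      n_samples_dropped = sc$dropped, mean_silhouette = sc$ss,
      stringsAsFactors = FALSE)
    for (cp in c("caeca", "crop")) {
      sel <- md$compartment == cp
      sc <- score(md$sample_id[sel], as.character(md$day[sel]))
      rows[[length(rows) + 1]] <- data.frame(
        subset = name, labelling = paste0("day:", cp),
        n_genera = length(sub$genera), n_samples = sc$n,
        n_samples_dropped = sc$dropped, mean_silhouette = sc$ss,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
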