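#' Construct a taxonomic profile for one sample under one sequencing strategy
#'
#' A taxonomic profile holds the genus-level read counts of a single sample
#' obtained by one sequencing strategy (16S amplicon or shotgun), together
#' with the phylum lineage of each genus and the total number of assigned
#' reads. Zero-count genera are not stored in the profile itself; the
#' dataset-wide genus axis lives in the enclosing [profile_set()].
#'
#' @param sample_id Character scalar identifying the sample.
#' @param strategy One of `"16S"` or `"shotgun"`.
#' @param counts Named non-negative integer vector of reads per genus.
#'   Entries equal to zero are dropped.
#' @param lineage Named character vector mapping genus name to phylum name.
#'   Must cover every genus with a positive count.
#' @return An object of class `taxonomic_profile` with elements `sample_id`,
#'   `strategy`, `counts` (positive counts only), `lineage` and
#'   `total_reads`.
#' @export
taxonomic_profile <- function(sample_id, strategy, counts, lineage) {
  strategy <- match.arg(strategy, c("16S", "shotgun"))
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("counts must be uniquely named by genus")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts <- counts[counts > 0]
  missing_lin <- setdiff(names(counts), names(lineage))
  if (length(missing_lin))
    stop("missing lineage for genera: ", paste(missing_lin, collapse = ", "))
  structure(
    list(
      sample_id = sample_id,
      strategy = strategy,
      counts = counts,
      lineage = lineage[names(counts)],
      total_reads = sum(counts)
    ),
    class = "taxonomic_profile"
  )
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat(sprintf(
    "<taxonomic_profile> %s [%s]: %d genera, %d reads\n",
    x$sample_id, x$strategy, length(x$counts), x$total_reads
  ))
  invisible(x)
}

#' Aggregate a profile's genus counts to another taxonomic rank
#'
#' @param profile A [taxonomic_profile()].
#' @param rank `"genus"` (identity) or `"phylum"` (sum member-genus counts).
#' @return Named count vector at the requested rank.
#' @export
rank_counts <- function(profile, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  if (rank == "genus") return(profile$counts)
  tapply(profile$counts, profile$lineage[names(profile$counts)], sum)
}

#' Bundle taxonomic profiles with sample metadata
#'
#' Validates that every profile has exactly one metadata row, that metadata
#' values are in range (compartment caeca/crop, day 1/14/35) and that each
#' pair id refers to at most one profile per strategy. The per-strategy genus
#' universe (union of all support sets, plus any all-zero genera declared in
#' the input tables) is computed here so that all downstream analyses share
#' one coordinate system.
#'
#' @param profiles List of [taxonomic_profile()] objects.
#' @param metadata Data frame with columns `sample_id`, `strategy`,
#'   `compartment`, `day`, `pair_id`.
#' @param extra_universe Optional named list (`"16S"`, `"shotgun"`) of genus
#'   names to keep on the axis even if undetected everywhere (e.g. all-zero
#'   rows of an input table).
#' @return An object of class `profile_set` with elements `profiles` (named
#'   by sample id), `metadata`, `universe` (list by strategy) and `lineage`
#'   (named character vector over the union of genera).
#' @export
profile_set <- function(profiles, metadata, extra_universe = NULL) {
  metadata <- validate_metadata(metadata)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate profile sample ids")
  names(profiles) <- ids
  missing_meta <- setdiff(ids, metadata$sample_id)
  if (length(missing_meta))
    stop("samples present in counts but not in metadata: ",
         paste(missing_meta, collapse = ", "))
  # strategy recorded in metadata must agree with the profile
  strat <- vapply(profiles, function(p) p$strategy, character(1))
  meta_strat <- metadata$strategy[match(ids, metadata$sample_id)]
  if (any(strat != meta_strat))
    stop("strategy mismatch between profiles and metadata for: ",
         paste(ids[strat != meta_strat], collapse = ", "))
  universe <- list()
  lineage <- character(0)
  for (s in c("16S", "shotgun")) {
    gen <- unique(unlist(lapply(
      profiles[strat == s], function(p) names(p$counts)
    ), use.names = FALSE))
    universe[[s]] <- sort(unique(c(gen, extra_universe[[s]])))
  }
  for (p in profiles) {
    lineage[names(p$lineage)] <- p$lineage
  }
  structure(
    list(profiles = profiles, metadata = metadata,
         universe = universe, lineage = lineage),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf(
    "<profile_set> %d profiles (%d 16S, %d shotgun), %d metadata rows\n",
    length(x$profiles),
    sum(vapply(x$profiles, function(p) p$strategy == "16S", logical(1))),
    sum(vapply(x$profiles, function(p) p$strategy == "shotgun", logical(1))),
    nrow(x$metadata)
  ))
  invisible(x)
}

validate_metadata <- function(metadata) {
  required <- c("sample_id", "strategy", "compartment", "day", "pair_id")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  metadata <- as.data.frame(metadata)[required]
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$pair_id <- as.character(metadata$pair_id)
  metadata$day <- suppressWarnings(as.integer(as.character(metadata$day)))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad_strat <- !metadata$strategy %in% c("16S", "shotgun")
  if (any(bad_strat))
    stop("unknown strategy for: ",
         paste(metadata$sample_id[bad_strat], collapse = ", "))
  bad_comp <- !metadata$compartment %in% c("caeca", "crop")
  if (any(bad_comp))
    stop("unknown compartment for: ",
         paste(metadata$sample_id[bad_comp], collapse = ", "))
  bad_day <- is.na(metadata$day) | !metadata$day %in% c(1L, 14L, 35L)
  if (any(bad_day))
    stop("day must be one of 1, 14, 35; offending samples: ",
         paste(metadata$sample_id[bad_day], collapse = ", "))
  dup <- duplicated(metadata[c("pair_id", "strategy")])
  if (any(dup))
    stop("pair_id with more than one profile of the same strategy: ",
         paste(unique(metadata$pair_id[dup]), collapse = ", "))
  metadata
}

#' Read a genus-level count table
#'
#' The expected format is a UTF-8 tab-separated table whose first column is
#' `genus`, second column `phylum`, and remaining columns one sample each
#' with integer read counts. Genera with all-zero rows stay on the genus
#' universe but do not enter any profile's support.
#'
#' @param path Path to the TSV file.
#' @param strategy Sequencing strategy of every sample in the table
#'   (`"16S"` or `"shotgun"`).
#' @return A list with `profiles` (list of [taxonomic_profile()]),
#'   `universe` (all genus names in the table) and `lineage`.
#' @export
read_count_table <- function(path, strategy) {
  strategy <- match.arg(strategy, c("16S", "shotgun"))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           colClasses = "character")
  if (ncol(tab) < 3 || names(tab)[1] != "genus" || names(tab)[2] != "phylum")
    stop("count table must start with columns 'genus' and 'phylum'")
  genera <- tab$genus
  dup <- genera[duplicated(genera)]
  if (length(dup))
    stop("duplicate genus rows: ", paste(unique(dup), collapse = ", "))
  lineage <- stats::setNames(tab$phylum, genera)
  sample_ids <- names(tab)[-(1:2)]
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(counts), nrow = nrow(counts)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer or negative count '%s' at genus '%s', sample '%s'",
      counts[bad[1, 1], bad[1, 2]], genera[bad[1, 1]], sample_ids[bad[1, 2]]
    ))
  }
  profiles <- lapply(seq_along(sample_ids), function(j) {
    taxonomic_profile(sample_ids[j], strategy,
                      stats::setNames(num[, j], genera), lineage)
  })
  list(profiles = profiles, universe = genera, lineage = lineage)
}

#' Write a genus-level count table
#'
#' Inverse of [read_count_table()]: writes all profiles of one strategy as a
#' genera x samples TSV with `genus` and `phylum` lead columns. Genera in
#' `universe` but detected nowhere are written as all-zero rows so a
#' round trip preserves the genus axis.
#'
#' @param profiles List of [taxonomic_profile()] of a single strategy.
#' @param path Output file path.
#' @param universe Optional character vector of genus names fixing row order
#'   and including all-zero genera; defaults to the union of supports.
#' @param lineage Optional genus-to-phylum map covering `universe`.
#' @return Invisibly, the path.
#' @export
write_count_table <- function(profiles, path, universe = NULL,
                              lineage = NULL) {
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(profiles, function(p)
      names(p$counts)), use.names = FALSE)))
  if (is.null(lineage)) {
    lineage <- character(0)
    for (p in profiles) lineage[names(p$lineage)] <- p$lineage
  }
  mat <- vapply(profiles, function(p) {
    v <- stats::setNames(integer(length(universe)), universe)
    v[names(p$counts)] <- as.integer(p$counts)
    v
  }, integer(length(universe)))
  mat <- matrix(mat, nrow = length(universe),
                dimnames = list(universe,
                                vapply(profiles, `[[`, character(1),
                                       "sample_id")))
  out <- data.frame(genus = universe,
                    phylum = unname(lineage[universe]),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' @param path Path to a TSV with columns `sample_id`, `strategy`,
#'   `compartment`, `day`, `pair_id`.
#' @return A validated metadata data frame (possibly empty, with a warning).
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           colClasses = "character")
  if (nrow(tab) == 0) {
    warning("metadata file ", path, " is empty")
    return(data.frame(sample_id = character(0), strategy = character(0),
                      compartment = character(0), day = integer(0),
                      pair_id = character(0)))
  }
  validate_metadata(tab)
}

#' Assemble a profile set from count tables and metadata on disk
#'
#' @param counts_16s,counts_shotgun Paths to per-strategy count tables
#'   (either may be `NULL`).
#' @param metadata Path to the metadata TSV.
#' @return A [profile_set()].
#' @export
read_profile_set <- function(counts_16s = NULL, counts_shotgun = NULL,
                             metadata) {
  meta <- read_metadata(metadata)
  profiles <- list()
  extra <- list()
  if (!is.null(counts_16s)) {
    frag <- read_count_table(counts_16s, "16S")
    profiles <- c(profiles, frag$profiles)
    extra[["16S"]] <- frag$universe
  }
  if (!is.null(counts_shotgun)) {
    frag <- read_count_table(counts_shotgun, "shotgun")
    profiles <- c(profiles, frag$profiles)
    extra[["shotgun"]] <- frag$universe
  }
  profile_set(profiles, meta, extra_universe = extra)
}

#' Pair the 16S and shotgun profiles of each biological sample
#'
#' @param set A [profile_set()].
#' @return A list with `pairs` (list of `sample_pair` objects, one per
#'   pair id having both strategies) and `unpaired` (sample ids whose mate
#'   is absent; reported, never silently dropped). Each `sample_pair` holds
#'   the two profiles plus the common / 16S-only / shotgun-only genus
#'   partition of its detected-genus union.
#' @export
pair_profiles <- function(set) {
  stopifnot(inherits(set, "profile_set"))
  md <- set$metadata
  pairs <- list()
  unpaired <- character(0)
  for (pid in unique(md$pair_id)) {
    rows <- md[md$pair_id == pid, ]
    id16 <- rows$sample_id[rows$strategy == "16S"]
    idsg <- rows$sample_id[rows$strategy == "shotgun"]
    if (length(id16) == 1 && length(idsg) == 1) {
      p16 <- set$profiles[[id16]]
      psg <- set$profiles[[idsg]]
      g16 <- names(p16$counts)
      gsg <- names(psg$counts)
      pairs[[pid]] <- structure(
        list(pair_id = pid,
             profile_16s = p16,
             profile_shotgun = psg,
             compartment = rows$compartment[1],
             day = rows$day[1],
             common = intersect(g16, gsg),
             only_16s = setdiff(g16, gsg),
             only_shotgun = setdiff(gsg, g16)),
        class = "sample_pair"
      )
    } else {
      unpaired <- c(unpaired, rows$sample_id)
    }
  }
  list(pairs = pairs, unpaired = unpaired)
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf(
    "<sample_pair> %s (%s, day %d): %d common, %d 16S-only, %d shotgun-only genera\n",
    x$pair_id, x$compartment, x$day, length(x$common),
    length(x$only_16s), length(x$only_shotgun)
  ))
  invisible(x)
}

#' Extract a genus x sample count matrix for one strategy
#'
#' Rows follow the strategy's genus universe (zeros for undetected genera),
#' columns are the selected samples.
#'
#' @param set A [profile_set()].
#' @param strategy `"16S"` or `"shotgun"`.
#' @param samples Optional character vector of sample ids (default: all
#'   samples of the strategy, in metadata order).
#' @return Integer matrix, genera x samples.
#' @export
profile_matrix <- function(set, strategy = c("16S", "shotgun"),
                           samples = NULL) {
  strategy <- match.arg(strategy)
  md <- set$metadata
  if (is.null(samples))
    samples <- md$sample_id[md$strategy == strategy]
  universe <- set$universe[[strategy]]
  mat <- matrix(0L, nrow = length(universe), ncol = length(samples),
                dimnames = list(universe, samples))
  for (id in samples) {
    p <- set$profiles[[id]]
    if (is.null(p)) stop("unknown sample id: ", id)
    if (p$strategy != strategy)
      stop("sample ", id, " is not a ", strategy, " profile")
    mat[names(p$counts), id] <- as.integer(p$counts)
  }
  mat
}

#' Restrict a profile set to a subset of samples
#'
#' @param set A [profile_set()].
#' @param sample_ids Sample ids to keep.
#' @return A new [profile_set()]; the genus universes are recomputed but any
#'   genus of the original universes is retained (zero-count genera stay on
#'   the axis).
#' @export
subset_samples <- function(set, sample_ids) {
  keep <- set$metadata$sample_id %in% sample_ids
  profile_set(set$profiles[set$metadata$sample_id[keep]],
              set$metadata[keep, , drop = FALSE],
              extra_universe = set$universe)
}
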