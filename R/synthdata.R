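# Paired-profile simulator: lognormal community, per-genus 16S bias,
# primer dropout (shotgun-exclusive) and database-phantom (16S-exclusive)
# genera, condition-dependent fold changes, multinomial read sampling.

#' Simulation design for paired 16S/shotgun datasets
#'
#' Collects every knob of the paired-profile simulator. The defaults emulate
#' the structure of a chicken-gut benchmark dataset: 78 paired samples over
#' two gut compartments (caeca: 4/16/20 and crop: 5/15/18 replicates at
#' rearing days 1/14/35), several hundred genera with lognormal abundances,
#' 16S depths near the nominal MiSeq output of ~187,500 reads per sample and
#' shotgun depths spanning two hundred thousand to five million reads (so
#' that roughly a quarter of shotgun samples fall below the 500,000-read
#' quality threshold, as in the real data).
#'
#' @param n_genera Number of genera in the true community (>= 2).
#' @param n_phyla Number of phyla the genera are assigned to.
#' @param log_mean,log_sd Mean and sd of log genus abundance (natural log)
#'   before normalization to proportions.
#' @param replicates Named list `caeca`/`crop` of named integer vectors
#'   (names `"1"`, `"14"`, `"35"`) giving replicates per cell.
#' @param depth_16s Length-2 range; 16S depths are uniform over it.
#' @param depth_shotgun Length-2 range; shotgun depths are log-uniform over
#'   it.
#' @param low_depth_fraction Optional fraction in `[0,1]`. When set, exactly
#'   `round(fraction * n_samples)` shotgun samples get depths log-uniform on
#'   `[depth_shotgun[1], 500000)` and the rest on `[500000,
#'   depth_shotgun[2]]`; when `NULL` depths are log-uniform over the full
#'   range.
#' @param compartment_affected,day_affected Fraction of (non-phantom) genera
#'   receiving a fold change for the compartment and day contrasts.
#' @param compartment_lfc_sd,day_lfc_sd SD of the normal distribution (log2
#'   scale, mean 0) the true fold changes are drawn from.
#' @param dropout_fraction Fraction of genera invisible to 16S (bias factor
#'   0; shotgun-exclusive in expectation).
#' @param phantom_fraction Fraction of genera observable only by 16S,
#'   emulating reference-database disagreement; drawn from the low-abundance
#'   half of the community and carrying no condition signal.
#' @param bias_log_sd SD (natural log) of the lognormal 16S bias factor
#'   around 1 for non-dropout genera.
#' @param seed Integer seed; one global seed per dataset, with per-sample
#'   substreams derived deterministically from (seed, sample id).
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genera = 400,
                              n_phyla = 14,
                              log_mean = 0,
                              log_sd = 2.5,
                              replicates = list(
                                caeca = c("1" = 4, "14" = 16, "35" = 20),
                                crop = c("1" = 5, "14" = 15, "35" = 18)
                              ),
                              depth_16s = c(150000, 200000),
                              depth_shotgun = c(200000, 5000000),
                              low_depth_fraction = NULL,
                              compartment_affected = 0.5,
                              compartment_lfc_sd = 2,
                              day_affected = 0.2,
                              day_lfc_sd = 1,
                              dropout_fraction = 0.3,
                              phantom_fraction = 0.05,
                              bias_log_sd = 0.5,
                              seed = 1L) {
  design <- list(
    n_genera = n_genera, n_phyla = n_phyla,
    log_mean = log_mean, log_sd = log_sd,
    replicates = replicates,
    depth_16s = depth_16s, depth_shotgun = depth_shotgun,
    low_depth_fraction = low_depth_fraction,
    compartment_affected = compartment_affected,
    compartment_lfc_sd = compartment_lfc_sd,
    day_affected = day_affected, day_lfc_sd = day_lfc_sd,
    dropout_fraction = dropout_fraction,
    phantom_fraction = phantom_fraction,
    bias_log_sd = bias_log_sd,
    seed = as.integer(seed)
  )
  validate_design(design)
  structure(design, class = "simulation_design")
}

validate_design <- function(d) {
  if (d$n_genera < 2) stop("n_genera must be at least 2")
  fracs <- c(d$compartment_affected, d$day_affected,
             d$dropout_fraction, d$phantom_fraction)
  if (!is.null(d$low_depth_fraction))
    fracs <- c(fracs, d$low_depth_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  if (any(c(d$depth_16s, d$depth_shotgun) < 1))
    stop("depths must be positive")
  if (d$dropout_fraction + d$phantom_fraction > 1)
    stop("dropout and phantom sets cannot cover more than all genera")
  invisible(d)
}

# Deterministic 31-bit hash of (seed, string) for per-sample RNG substreams.
substream_seed <- function(seed, id) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(id)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Draw a true community with lognormal abundances, bias and exclusivity
#'
#' Genus proportions are lognormal on the log scale, so the full relative
#' species abundance distribution is near-symmetric once log-transformed and
#' any left-tail truncation seen in a sampled profile is attributable to
#' finite read depth. A `dropout_fraction` of genera receive a 16S bias
#' factor of exactly 0 (never amplified; shotgun-exclusive); the remaining
#' bias factors are lognormal around 1. A disjoint `phantom_fraction` of
#' genera, drawn from the low-abundance half, is observable only by 16S.
#'
#' @param design A [simulation_design()].
#' @return A `true_community` list: `proportions` (named, sums to 1),
#'   `lineage`, `bias` (b_g >= 0), `phantom` (logical), and the design seed.
#' @export
generate_true_community <- function(design) {
  validate_design(design)
  with_local_seed(substream_seed(design$seed, "community"), {
    genera <- sprintf("g%03d", seq_len(design$n_genera))
    phyla <- sprintf("p%02d", seq_len(design$n_phyla))
    lineage <- stats::setNames(sample(phyla, design$n_genera, replace = TRUE),
                               genera)
    raw <- stats::rlnorm(design$n_genera, design$log_mean, design$log_sd)
    props <- stats::setNames(raw / sum(raw), genera)
    n_drop <- round(design$dropout_fraction * design$n_genera)
    n_phantom <- round(design$phantom_fraction * design$n_genera)
    dropout <- sample(genera, n_drop)
    low_half <- setdiff(names(sort(props))[seq_len(design$n_genera %/% 2)],
                        dropout)
    if (length(low_half) < n_phantom)
      low_half <- setdiff(genera, dropout)
    phantom_set <- sample(low_half, n_phantom)
    bias <- stats::setNames(
      stats::rlnorm(design$n_genera, 0, design$bias_log_sd), genera)
    bias[dropout] <- 0
    phantom <- stats::setNames(genera %in% phantom_set, genera)
    bias[phantom] <- 1
    structure(
      list(proportions = props, lineage = lineage, bias = bias,
           phantom = phantom, seed = design$seed),
      class = "true_community"
    )
  })
}

#' Apply condition-dependent fold changes to a true community
#'
#' A random fraction of non-phantom genera have their proportion multiplied
#' by `2^LFC` (LFC drawn from a centred normal on the log2 scale) in the
#' non-reference condition levels, after which proportions are renormalized.
#' The per-genus true LFC relative to the reference level is recorded as
#' ground truth. For the compartment contrast the reference level is caeca;
#' for the day contrast the reference is day 14, with independent effect
#' sets for day 1 and day 35 (day 1 communities differ in their own right).
#'
#' @param base A `true_community` from [generate_true_community()].
#' @param contrast `"compartment"` or `"day"`.
#' @param design A [simulation_design()].
#' @return A list with `levels` (named list of `true_community`, one per
#'   condition level) and `true_lfc` (named vector, the recorded log2 fold
#'   change of the tested contrast: crop vs caeca, or day 35 vs day 14;
#'   zero for unaffected genera).
#' @export
apply_condition_effects <- function(base, contrast = c("compartment", "day"),
                                    design) {
  contrast <- match.arg(contrast)
  affected_frac <- switch(contrast,
                          compartment = design$compartment_affected,
                          day = design$day_affected)
  lfc_sd <- switch(contrast,
                   compartment = design$compartment_lfc_sd,
                   day = design$day_lfc_sd)
  eligible <- names(base$proportions)[!base$phantom]
  level_names <- switch(contrast,
                        compartment = c("caeca", "crop"),
                        day = c("14", "1", "35"))
  with_local_seed(substream_seed(design$seed, paste0("effects-", contrast)), {
    levels_out <- list()
    levels_out[[level_names[1]]] <- base
    true_lfc <- stats::setNames(numeric(length(base$proportions)),
                                names(base$proportions))
    for (lev in level_names[-1]) {
      n_aff <- round(affected_frac * length(eligible))
      affected <- sample(eligible, n_aff)
      lfc <- stats::setNames(numeric(length(base$proportions)),
                             names(base$proportions))
      lfc[affected] <- stats::rnorm(n_aff, 0, lfc_sd)
      mass <- base$proportions * 2^lfc
      mod <- base
      mod$proportions <- mass / sum(mass)
      levels_out[[lev]] <- mod
      if (lev %in% c("crop", "35")) true_lfc <- lfc
    }
    list(levels = levels_out, true_lfc = true_lfc)
  })
}

#' Simulate a shotgun profile by multinomial read sampling
#'
#' Reads are distributed over genera as a single multinomial draw from the
#' community proportions: shotgun sequencing is modeled as unbiased random
#' fragmentation, so all strategy distortions live in the 16S bias factors.
#' Phantom (16S-exclusive) genera are never sampled.
#'
#' @param community A `true_community`.
#' @param depth Positive integer total read count.
#' @param sample_id Sample identifier for the profile.
#' @param seed Optional integer; when given, sampling uses a local RNG
#'   stream seeded with it.
#' @return A [taxonomic_profile()] with `total_reads == depth`.
#' @export
simulate_shotgun_profile <- function(community, depth, sample_id = "shotgun",
                                     seed = NULL) {
  stopifnot(depth >= 1)
  p <- community$proportions
  p[community$phantom] <- 0
  if (sum(p) == 0) stop("no shotgun-observable genera")
  draw <- function() {
    stats::setNames(
      as.integer(stats::rmultinom(1, size = depth, prob = p)), names(p))
  }
  counts <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  taxonomic_profile(sample_id, "shotgun", counts, community$lineage)
}

#' Simulate a 16S profile with primer bias and phantom genera
#'
#' Sampling proportions are proportional to `p_g * b_g` over non-phantom
#' genera, plus the phantom genera at their own (small) community
#' proportions; genera with bias 0 are never observed. Reduces exactly to
#' [simulate_shotgun_profile()] when all biases are 1 and no genus is
#' phantom.
#'
#' @inheritParams simulate_shotgun_profile
#' @return A [taxonomic_profile()] with strategy `"16S"`.
#' @export
simulate_16s_profile <- function(community, depth, sample_id = "16S",
                                 seed = NULL) {
  stopifnot(depth >= 1)
  w <- community$proportions * community$bias
  w[community$phantom] <- community$proportions[community$phantom]
  if (sum(w) == 0)
    stop("all bias factors are zero and no phantom genera: nothing to sample")
  draw <- function() {
    stats::setNames(
      as.integer(stats::rmultinom(1, size = depth, prob = w)), names(w))
  }
  counts <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  taxonomic_profile(sample_id, "16S", counts, community$lineage)
}

draw_depths <- function(design, sample_ids) {
  n <- length(sample_ids)
  with_local_seed(substream_seed(design$seed, "depths"), {
    d16 <- round(stats::runif(n, design$depth_16s[1], design$depth_16s[2]))
    lo <- log(design$depth_shotgun[1])
    hi <- log(design$depth_shotgun[2])
    if (is.null(design$low_depth_fraction)) {
      dsg <- round(exp(stats::runif(n, lo, hi)))
    } else {
      n_low <- round(design$low_depth_fraction * n)
      cut <- log(5e5)
      low_ids <- sample(n, n_low)
      dsg <- round(exp(stats::runif(n, cut, hi)))
      dsg[low_ids] <- round(exp(stats::runif(n_low, lo, min(cut, hi))))
    }
    list(d16 = stats::setNames(d16, sample_ids),
         dsg = stats::setNames(dsg, sample_ids))
  })
}

#' Generate a full paired 16S/shotgun dataset with ground truth
#'
#' Builds the true community, applies compartment and day effects (the day
#' effect sets are shared across compartments so the day contrast is
#' consistent whether pooled or stratified), draws per-sample depths, and
#' simulates one 16S and one shotgun profile per biological sample using a
#' deterministic per-sample RNG substream.
#'
#' @param design A [simulation_design()].
#' @return A list with `set` (a [profile_set()] with both strategies),
#'   `truth` (data frame: genus, phylum, true proportion per condition cell,
#'   bias, phantom flag, true LFC per contrast) and `design`.
#' @export
generate_paired_dataset <- function(design = simulation_design()) {
  validate_design(design)
  base <- generate_true_community(design)
  comp <- apply_condition_effects(base, "compartment", design)
  # day effects drawn once, then applied on top of each compartment level
  day_fx <- apply_condition_effects(base, "day", design)
  communities <- list()
  for (cp in c("caeca", "crop")) {
    for (dy in c("1", "14", "35")) {
      cm <- comp$levels[[cp]]
      mass <- cm$proportions *
        day_fx$levels[[dy]]$proportions / base$proportions
      cm$proportions <- mass / sum(mass)
      communities[[paste(cp, dy, sep = "_")]] <- cm
    }
  }
  # sample layout
  meta <- do.call(rbind, lapply(c("caeca", "crop"), function(cp) {
    do.call(rbind, lapply(c("1", "14", "35"), function(dy) {
      n <- unname(design$replicates[[cp]][dy])
      if (is.null(n) || is.na(n) || n == 0) return(NULL)
      pair_id <- sprintf("%s%s_d%s_r%02d", substr(cp, 1, 2),
                         "", dy, seq_len(n))
      data.frame(pair_id = pair_id, compartment = cp,
                 day = as.integer(dy), stringsAsFactors = FALSE)
    }))
  }))
  depths <- draw_depths(design, meta$pair_id)
  profiles <- vector("list", 2 * nrow(meta))
  md_rows <- vector("list", 2 * nrow(meta))
  for (i in seq_len(nrow(meta))) {
    pid <- meta$pair_id[i]
    comm <- communities[[paste(meta$compartment[i], meta$day[i], sep = "_")]]
    id16 <- paste0(pid, "_16S")
    idsg <- paste0(pid, "_sg")
    profiles[[2 * i - 1]] <- simulate_16s_profile(
      comm, depths$d16[[pid]], id16,
      seed = substream_seed(design$seed, id16))
    profiles[[2 * i]] <- simulate_shotgun_profile(
      comm, depths$dsg[[pid]], idsg,
      seed = substream_seed(design$seed, idsg))
    md_rows[[2 * i - 1]] <- data.frame(
      sample_id = id16, strategy = "16S", compartment = meta$compartment[i],
      day = meta$day[i], pair_id = pid, stringsAsFactors = FALSE)
    md_rows[[2 * i]] <- data.frame(
      sample_id = idsg, strategy = "shotgun",
      compartment = meta$compartment[i], day = meta$day[i], pair_id = pid,
      stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, md_rows)
  set <- profile_set(profiles, metadata)
  genera <- names(base$proportions)
  truth <- data.frame(genus = genera,
                      phylum = unname(base$lineage[genera]),
                      stringsAsFactors = FALSE)
  for (cell in names(communities))
    truth[[paste0("prop_", cell)]] <-
      unname(communities[[cell]]$proportions[genera])
  truth$bias <- unname(base$bias[genera])
  truth$phantom <- unname(base$phantom[genera])
  truth$lfc_compartment <- unname(comp$true_lfc[genera])
  truth$lfc_day <- unname(day_fx$true_lfc[genera])
  list(set = set, truth = truth, design = design)
}

#' Write a simulated dataset to disk in the package's tabular formats
#'
#' Writes `counts_16s.tsv`, `counts_shotgun.tsv`, `metadata.tsv`,
#' `ground_truth.tsv` and `design.yaml` (all parameters plus the seed).
#'
#' @param dataset Result of [generate_paired_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set <- dataset$set
  strat <- vapply(set$profiles, `[[`, character(1), "strategy")
  write_count_table(set$profiles[strat == "16S"],
                    file.path(dir, "counts_16s.tsv"),
                    universe = set$universe[["16S"]],
                    lineage = set$lineage)
  write_count_table(set$profiles[strat == "shotgun"],
                    file.path(dir, "counts_shotgun.tsv"),
                    universe = set$universe[["shotgun"]],
                    lineage = set$lineage)
  utils::write.table(set$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  design <- dataset$design
  design$replicates <- lapply(design$replicates, as.list)
  yaml::write_yaml(unclass(design), file.path(dir, "design.yaml"))
  invisible(dir)
}
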