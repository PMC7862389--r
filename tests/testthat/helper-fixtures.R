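# Shared fixture builders: tiny profiles, pairs and count tables built in
# code, plus an independent per-genus NB likelihood maximizer used as an
# oracle for the vectorized Wald engine.

make_profile <- function(counts, sample_id = "s1", strategy = "shotgun",
                         phyla = NULL) {
  if (is.null(names(counts)))
    names(counts) <- sprintf("g%02d", seq_along(counts))
  if (is.null(phyla)) phyla <- rep("pA", length(counts))
  taxonomic_profile(sample_id, strategy, counts,
                    stats::setNames(phyla, names(counts)))
}

make_pair <- function(counts_16s, counts_shotgun, pair_id = "p1",
                      compartment = "caeca", day = 14L) {
  p16 <- make_profile(counts_16s, paste0(pair_id, "_16S"), "16S")
  psg <- make_profile(counts_shotgun, paste0(pair_id, "_sg"), "shotgun")
  g16 <- names(p16$counts); gsg <- names(psg$counts)
  structure(
    list(pair_id = pair_id, profile_16s = p16, profile_shotgun = psg,
         compartment = compartment, day = day,
         common = intersect(g16, gsg),
         only_16s = setdiff(g16, gsg),
         only_shotgun = setdiff(gsg, g16)),
    class = "sample_pair"
  )
}

make_metadata <- function(pair_ids, compartment = "caeca", day = 14L) {
  do.call(rbind, lapply(seq_along(pair_ids), function(i) {
    data.frame(
      sample_id = paste0(pair_ids[i], c("_16S", "_sg")),
      strategy = c("16S", "shotgun"),
      compartment = rep(compartment, length.out = 2),
      day = day, pair_id = pair_ids[i], stringsAsFactors = FALSE)
  }))
}

# Independent oracle: per-genus NB log-likelihood maximized with optim()
# over (log mu0, log fold change); same model, different optimizer.
nb_mle_oracle <- function(k, sf, alpha, x) {
  nll <- function(par) {
    mu <- sf * exp(par[1] + par[2] * x)
    -sum(stats::dnbinom(k, mu = mu, size = 1 / alpha, log = TRUE))
  }
  init <- c(log(max(mean(k / sf), 0.1)), 0)
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  hess <- stats::optimHess(fit$par, nll)
  se <- sqrt(diag(solve(hess)))
  list(lfc = fit$par[2] / log(2), se = se[2] / log(2))
}
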