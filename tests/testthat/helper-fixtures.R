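# Shared fixtures built in code.

# Quick constructor for sighting-record data.frames.
rec <- function(animal_id, birth_colony, birth_year, obs_year, obs_colony) {
  data.frame(animal_id = animal_id, birth_colony = birth_colony,
             birth_year = as.integer(birth_year),
             obs_year = as.integer(obs_year), obs_colony = obs_colony)
}

bind_rec <- function(...) {
  out <- do.call(rbind, list(...))
  attr(out, "colonies") <- c("AN", "PB")
  out
}

# Minimal sighting histories consistent with a cohort dispersal table: one
# breeding-age record per observed breeder at the colony of assignment.
records_from_cohorts <- function(tab, obs_age = 3) {
  pieces <- list()
  other <- function(cc) setdiff(unique(tab$colony), cc)
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    n_res <- row$resident
    n_emi <- row$emigrant
    if (n_res + n_emi == 0) next
    ids <- sprintf("%s%d-%03d", row$colony, row$birth_year,
                   seq_len(n_res + n_emi))
    pieces[[k]] <- rec(ids, row$colony, row$birth_year,
                       row$birth_year + obs_age,
                       c(rep(row$colony, n_res),
                         rep(other(row$colony), n_emi)))
  }
  out <- do.call(rbind, pieces)
  attr(out, "colonies") <- unique(tab$colony)
  out
}

tagged_from_cohorts <- function(tab) {
  data.frame(birth_year = tab$birth_year, colony = tab$colony,
             n_tagged = tab$tagged)
}

# Detection posterior rebuilt from the published study inputs: Beta
# posterior from the reappearance counts, Normal return-rate posterior
# from the published estimate and interval.
study_detection <- function(M = 2e4, seed = 42) {
  rr <- seal_return_rate()
  se <- (rr$upper - rr$lower) / (2 * stats::qnorm(0.975))
  fits <- stats::setNames(
    lapply(seq_len(2), function(i) return_rate_fit(rr$estimate[i], se[i])),
    rr$colony)
  estimate_detection(seal_reappearance(), fits, M = M, seed = seed)
}
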