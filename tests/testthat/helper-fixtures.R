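# Shared fixtures and independent oracles, built in code at test time.

# A minimal scan table around a given thickness matrix (scans x regions).
scan_table_from_matrix <- function(values, ages = seq_len(nrow(values)),
                                   sex = rep(0L, nrow(values)),
                                   cohort = rep(0L, nrow(values)),
                                   scanner = rep(0L, nrow(values)),
                                   participant_id = sprintf("P%03d", seq_len(nrow(values)))) {
  n <- nrow(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("R%03d", seq_len(ncol(values)))
  }
  cbind(data.frame(participant_id = participant_id,
                   scan_id = sprintf("S%03d", seq_len(n)),
                   age = ages, sex = sex, cohort = cohort, scanner = scanner,
                   stringsAsFactors = FALSE),
        as.data.frame(values))
}

# A bin covering a chosen subset of a scan table's scans.
bin_of <- function(scan_table, rows = seq_len(nrow(scan_table))) {
  list(index = 1L,
       scan_id = scan_table$scan_id[rows],
       participant_id = scan_table$participant_id[rows],
       age = scan_table$age[rows],
       median_age = stats::median(scan_table$age[rows]))
}

# Dummy age-sorted scan pool of M unique participants (windowing tests).
dummy_pool <- function(M, age_min = 8.5, age_max = 14.5, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%04d", seq_len(M)),
             scan_id = sprintf("S%04d", seq_len(M)),
             age = sort(stats::runif(M, age_min, age_max)),
             stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up oracle: largest k with
# p_(k) <= k * alpha / m rejects all p <= p_(k).
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- which(p[ord] <= seq_len(m) * alpha / m)
  if (length(k) == 0L) return(rep(FALSE, m))
  p <= p[ord][max(k)]
}

# Direct window-enumeration oracle for the number of bins.
enumerate_bins_oracle <- function(M, bin_size, step) {
  count <- 0L
  offset <- 0L
  last <- -1L
  while (offset + bin_size <= M) {
    count <- count + 1L
    last <- offset
    offset <- offset + step
  }
  if (last != M - bin_size) count <- count + 1L
  count
}

# Default synthetic study, generated once per test run and cached.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      parc <- generate_parcellation(60L, 7L, seed = 7)
      ds <- generate_dataset(scn_sim_config(seed = 11), parc)
      cache <<- list(parcellation = parc, scans = ds$scans, truth = ds$truth)
    }
    cache
  }
})
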