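#' Run the full structural-covariance-network analysis
#'
#' End-to-end orchestration: residualize thickness for covariates, then for
#' every sliding-window configuration build age bins, bootstrap-threshold a
#' correlation network per bin, compute graph metrics, fit null/linear/
#' smooth age trajectories for global, hub and modular metrics, and report
#' consensus findings across configurations. Optionally estimates
#' per-region thinning rates and tests their spatial correlation with
#' standardized degree in the oldest (and youngest) bins, and re-runs the
#' pipeline within each sex.
#'
#' All randomized stages derive their seeds deterministically from
#' \code{root_seed}, so a rerun with the same inputs reproduces identical
#' outputs.
#'
#' @param scan_table a scan table.
#' @param parcellation matching \code{"scn_parcellation"}.
#' @param bin_sizes,step_fractions window grid (defaults: the nine
#'   configurations \{70,80,90\} x \{20,25,30\}\%).
#' @param B,alpha bootstrap resamples and FDR level for edge thresholding.
#' @param delta_aic AIC margin for trajectory model selection.
#' @param consensus_fraction findings must appear in more than this
#'   fraction of configurations to be reported.
#' @param hub_threshold,hub_min_bins hub definition (z-degree > threshold
#'   in at least this many bins).
#' @param n_surr surrogate maps per hemisphere for the thinning test.
#' @param covariates covariates residualized out before network estimation
#'   and included in the thinning mixed model.
#' @param do_thinning,do_sex toggle the thinning-association and
#'   sex-stratified stages.
#' @param root_seed integer root seed.
#' @return A list of class \code{"scn_pipeline"}; see the elements
#'   \code{configs}, \code{per_config}, \code{trajectories},
#'   \code{consensus}, \code{hub_consensus}, \code{thinning}, \code{sex}.
#' @export
run_scn_pipeline <- function(scan_table, parcellation,
                             bin_sizes = c(70L, 80L, 90L),
                             step_fractions = c(0.20, 0.25, 0.30),
                             B = 1000L, alpha = 0.05,
                             delta_aic = 3, consensus_fraction = 0.5,
                             hub_threshold = 1, hub_min_bins = 2L,
                             n_surr = 1000L,
                             covariates = c("sex", "cohort", "scanner"),
                             do_thinning = TRUE, do_sex = FALSE,
                             root_seed = 1L) {
  check_scan_table(scan_table)
  if (!identical(region_columns(scan_table), parcellation$region_ids)) {
    stop_invalid("scan table regions do not match the parcellation")
  }
  configs <- window_configs(bin_sizes, step_fractions)
  resid <- residualize(scan_table, covariates)
  modules <- parcellation$modules
  P <- length(parcellation$region_ids)

  per_config <- list()
  traj_rows <- list()
  findings <- list()
  hub_flags <- matrix(FALSE, P, nrow(configs),
                      dimnames = list(parcellation$region_ids, configs$config_id))

  for (ci in seq_len(nrow(configs))) {
    cid <- configs$config_id[ci]
    bins <- build_bins(resid, configs$bin_size[ci], configs$step_fraction[ci])
    nb <- length(bins)
    networks <- vector("list", nb)
    med <- gd <- mc <- numeric(nb)
    z <- matrix(NA_real_, P, nb, dimnames = list(parcellation$region_ids, NULL))
    intra <- matrix(NA_real_, parcellation$n_modules, nb)
    n_pairs <- choose(parcellation$n_modules, 2)
    inter <- matrix(NA_real_, n_pairs, nb)
    for (i in seq_len(nb)) {
      net <- bootstrap_threshold(resid, bins[[i]], B = B, alpha = alpha,
                                 seed = derive_seed(root_seed, "boot", cid, i))
      networks[[i]] <- net
      med[i] <- bins[[i]]$median_age
      gd[i] <- global_density(net)
      mc[i] <- mean_correlation(net)
      z[, i] <- suppressWarnings(standardized_degree(net))
      md <- modular_density(net, modules)
      intra[, i] <- md$intra$value
      inter[, i] <- md$inter$value
    }
    pair_ids <- apply(utils::combn(sort(unique(modules)), 2), 2,
                      paste, collapse = "-")
    hubs <- identify_hubs(z, hub_threshold, min(hub_min_bins, nb))
    hub_flags[, ci] <- hubs$hub

    # trajectory fits: global metrics, hub z-degree, modular densities
    hub_idx <- which(hubs$hub)
    series <- c(list(global_density = gd, mean_correlation = mc),
                stats::setNames(
                  lapply(hub_idx, function(r) z[r, ]),
                  sprintf("z_degree[%s]", parcellation$region_ids[hub_idx])),
                stats::setNames(
                  lapply(seq_len(nrow(intra)), function(m) intra[m, ]),
                  paste0("norm_intra[", sort(unique(modules)), "]")),
                stats::setNames(
                  lapply(seq_len(nrow(inter)), function(k) inter[k, ]),
                  paste0("norm_inter[", pair_ids, "]")))
    for (mid in names(series)) {
      v <- series[[mid]]
      ok <- is.finite(v)
      if (sum(ok) < 4L || stats::sd(med[ok]) < 1e-12) next
      fit <- fit_trajectory(med[ok], v[ok], delta = delta_aic)
      traj_rows[[length(traj_rows) + 1L]] <- data.frame(
        config_id = cid, metric_id = mid,
        batch = if (grepl("^z_degree", mid)) "nodal"
                else if (grepl("^norm_", mid)) "modular" else "global",
        aic_null = fit$aic[["null"]], aic_linear = fit$aic[["linear"]],
        aic_smooth = fit$aic[["smooth"]], selected = fit$selected,
        smooth_p = fit$smooth_p, peak_age = fit$peak_age,
        net_change = fit$net_change, stringsAsFactors = FALSE)
      findings[[length(findings) + 1L]] <- data.frame(
        config_id = cid, metric_id = mid, selected = fit$selected,
        direction = if (fit$selected == "null") "flat"
                    else if (fit$net_change >= 0) "increase" else "decrease",
        stringsAsFactors = FALSE)
    }
    per_config[[cid]] <- list(bins = bins, networks = networks,
                              median_age = med, global_density = gd,
                              mean_correlation = mc, z_degree = z,
                              norm_intra = intra, norm_inter = inter,
                              hubs = hubs)
  }

  trajectories <- do.call(rbind, traj_rows)
  # FDR on smooth-term p-values within the nodal and modular batches,
  # separately per configuration
  trajectories$smooth_p_adj <- NA_real_
  for (cid in configs$config_id) {
    for (batch in c("nodal", "modular")) {
      sel <- which(trajectories$config_id == cid & trajectories$batch == batch &
                     !is.na(trajectories$smooth_p))
      if (length(sel) > 0L) {
        trajectories$smooth_p_adj[sel] <-
          fdr_correct(trajectories$smooth_p[sel])$adjusted
      }
    }
  }
  consensus <- consensus_report(do.call(rbind, findings),
                                n_configs = nrow(configs),
                                fraction = consensus_fraction)
  hub_consensus <- rowMeans(hub_flags) > consensus_fraction

  thinning <- NULL
  if (do_thinning) {
    rates <- fit_thinning_rates(scan_table, covariates)
    ensembles <- lapply(stats::setNames(nm = unique(parcellation$hemisphere)),
                        function(h) {
      idx <- which(parcellation$hemisphere == h)
      build_surrogates(rates$beta_age[idx], parcellation$distance[[h]],
                       n_surr = n_surr,
                       seed = derive_seed(root_seed, "surr", h))
    })
    assoc <- list()
    for (cid in configs$config_id) {
      pc <- per_config[[cid]]
      nb <- length(pc$bins)
      for (which_bin in c("oldest", "youngest")) {
        bi <- if (which_bin == "oldest") nb else 1L
        tests <- thinning_degree_association(rates, pc$z_degree[, bi],
                                             parcellation,
                                             surrogates = ensembles)
        for (h in names(tests)) {
          assoc[[length(assoc) + 1L]] <- data.frame(
            config_id = cid, which_bin = which_bin, hemisphere = h,
            bin_median_age = pc$median_age[bi],
            r = tests[[h]]$r_empirical, p = tests[[h]]$p,
            stringsAsFactors = FALSE)
        }
      }
    }
    assoc <- do.call(rbind, assoc)
    consistency <- stats::aggregate(
      list(n_significant = assoc$p < 0.05 & assoc$r < 0),
      by = assoc[, c("which_bin", "hemisphere")], FUN = sum)
    consistency$n_configs <- nrow(configs)
    thinning <- list(rates = rates, association = assoc,
                     consistency = consistency)
  }

  sex_results <- NULL
  if (do_sex) {
    sex_results <- list(runs = list(), comparisons = list())
    for (ci in seq_len(nrow(configs))) {
      cid <- configs$config_id[ci]
      runs <- lapply(stats::setNames(nm = sort(unique(scan_table$sex))),
                     function(sx) {
        stratified_pipeline(scan_table, sx, configs$bin_size[ci],
                            configs$step_fraction[ci], B = B, alpha = alpha,
                            modules = modules,
                            seed = derive_seed(root_seed, "sex", cid, sx))
      })
      sex_results$runs[[cid]] <- runs
      if (length(runs) == 2L && !runs[[1]]$skipped && !runs[[2]]$skipped) {
        for (metric in c("global_density", "mean_correlation")) {
          cmp <- sex_interaction_fit(runs[[1]]$median_age, runs[[1]][[metric]],
                                     runs[[2]]$median_age, runs[[2]][[metric]],
                                     delta = delta_aic)
          sex_results$comparisons[[length(sex_results$comparisons) + 1L]] <-
            data.frame(config_id = cid, metric_id = metric,
                       aic_shared = cmp$aic_shared,
                       aic_by_sex = cmp$aic_by_sex,
                       selected = cmp$selected, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(sex_results$comparisons) > 0L) {
      sex_results$comparisons <- do.call(rbind, sex_results$comparisons)
    }
  }

  structure(list(configs = configs, per_config = per_config,
                 trajectories = trajectories, consensus = consensus,
                 hub_consensus = hub_consensus, thinning = thinning,
                 sex = sex_results,
                 params = list(B = B, alpha = alpha, delta_aic = delta_aic,
                               consensus_fraction = consensus_fraction,
                               hub_threshold = hub_threshold,
                               hub_min_bins = hub_min_bins, n_surr = n_surr,
                               covariates = covariates,
                               root_seed = root_seed)),
            class = "scn_pipeline")
}

#' Write pipeline outputs to a directory with a hashed manifest
#'
#' Writes tidy CSVs for per-bin metrics, trajectory fits, consensus
#' findings and (when present) thinning associations, plus a
#' \code{manifest.json} listing each file with its MD5 hash. Reruns of the
#' pipeline with identical inputs and root seed produce byte-identical
#' files and hence identical manifests.
#'
#' @param result an \code{"scn_pipeline"} object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest as a named list of MD5 hashes.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cid in names(result$per_config)) {
    pc <- result$per_config[[cid]]
    rows[[cid]] <- data.frame(
      config_id = cid, bin_index = seq_along(pc$median_age),
      median_age = pc$median_age, global_density = pc$global_density,
      mean_correlation = pc$mean_correlation, stringsAsFactors = FALSE)
  }
  files <- character(0)
  wr <- function(obj, name) {
    path <- file.path(dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(do.call(rbind, rows), "global_metrics.csv")
  wr(result$trajectories, "trajectory_fits.csv")
  wr(result$consensus, "consensus.csv")
  if (!is.null(result$thinning)) {
    wr(result$thinning$rates, "thinning_rates.csv")
    wr(result$thinning$association, "thinning_association.csv")
  }
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(files)
  jsonlite::write_json(hashes, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(hashes)
}
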