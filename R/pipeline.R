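#' Default run configuration
#'
#' Plain list of stage parameters mirroring every documented default, with
#' a simulation block for demo runs. Write it to YAML for the command-line
#' wrapper, or edit in place.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, out_dir = "admixscan_out") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sim = list(K = 4, F = 0.2, n_ref = 20, n_adm = 15, L_bp = 10e6,
               n_sites = 4000, n_chr = 2, cM_per_Mb = 1,
               m = c(0.556, 0.332, 0.068, 0.044), g = 30, eps = 0.001),
    filters = list(depth_low = 1 / 3, depth_high = 3),
    windows = list(pi_win = 50000, pi_step = 20000, taj_win = 2000,
                   scan_win = 50000),
    paint = list(lambda_grid = c(1, 1.5, 2, 3, 5)),
    segments = list(f_min = 0.75, len_min = 1000, alpha = 0.01),
    dating = list(bin_cM = 0.05, max_cM = 10, d_min_cM = 0.5,
                  min_pairs = 50, max_sites = 2000),
    intersect = list(top_q = 0.01, min_methods = 2),
    roh = list(window_snp = 100, window_het = 1, window_threshold = 0.05,
               min_kb = 100, density_kb_per_snp = 200)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys missing from the file keep their documented defaults; unknown keys
#' raise an error.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(y), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in names(y)) {
    if (is.list(cfg[[k]])) {
      bad <- setdiff(names(y[[k]]), names(cfg[[k]]))
      if (length(bad))
        stop("unknown config keys in ", k, ": ", paste(bad, collapse = ", "))
      cfg[[k]][names(y[[k]])] <- y[[k]]
    } else cfg[[k]] <- y[[k]]
  }
  cfg
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Simulates panels and a single-pulse admixed cohort, then executes
#' every stage: hard filters, diversity and differentiation scans,
#' kinship, ROH, local-ancestry painting, ancestry-excess segments,
#' weighted-LD admixture dating, iHS and CLR sweep scans and the
#' top-quantile intersection. Writes TSV/BED/JSON artifacts plus
#' `summary.json` into `out_dir`. Identical seeds give byte-identical
#' outputs.
#'
#' @param config a `run_config` (default [default_config()]).
#' @return Invisibly, the summary list.
#' @export
run_demo <- function(config = default_config()) {
  run_pipeline(config)
}

#' @rdname run_demo
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[admixscan] %s", sprintf(...)))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_msg("%-10s %6.1fs", name, proc.time()[3] - t0)
    r
  }
  sim <- config$sim
  cfg <- sim_config(K = sim$K, F = sim$F, n_ref = sim$n_ref,
                    n_adm = sim$n_adm, L_bp = sim$L_bp,
                    n_sites = sim$n_sites, n_chr = sim$n_chr,
                    cM_per_Mb = sim$cM_per_Mb, m = sim$m, g = sim$g,
                    eps = sim$eps, seed = config$seed)
  panels <- stage("simulate", {
    p <- make_panels(cfg); p
  })
  truth <- stage("cohort", simulate_cohort(cfg, panels))
  export_truth(truth, file.path(out, "truth"))
  st <- truth$target

  wtab <- function(d, f) {
    write.table(format(d, trim = TRUE, digits = 10), file.path(out, f),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pw <- config$windows
  stats_out <- stage("stats", {
    pi_t <- pi_windows(st, win = pw$pi_win, step = pw$pi_step)
    pi_r <- pi_windows(panels$haps[[2]], win = pw$pi_win, step = pw$pi_step)
    taj <- tajimas_d(st, win = pw$taj_win)
    comb <- bind_samples(st, panels$haps[[2]])
    fst <- wc_fst_windows(comb, st$samples, panels$haps[[2]]$samples,
                          win = pw$pi_win, step = pw$pi_step)
    tpr <- theta_pi_ratio(pi_t, pi_r)
    kin <- suppressWarnings(king_kinship(st))
    wtab(pi_t, "pi_target.tsv"); wtab(taj, "tajimas_d.tsv")
    wtab(fst, "fst.tsv"); wtab(tpr, "theta_pi_ratio.tsv")
    wtab(kin, "kinship.tsv")
    list(pi_t = pi_t, taj = taj, fst = fst, tpr = tpr)
  })
  roh <- stage("roh", {
    r <- do.call(rbind, lapply(st$samples[1:min(3, length(st$samples))],
                               function(s) suppressWarnings(
                                 detect_roh(st, s,
                                   window_snp = config$roh$window_snp,
                                   window_het = config$roh$window_het,
                                   window_threshold =
                                     config$roh$window_threshold,
                                   min_kb = config$roh$min_kb,
                                   density_kb_per_snp =
                                     config$roh$density_kb_per_snp))))
    wtab(r, "roh.tsv"); r
  })
  painting <- stage("paint", paint_cohort(st, panels,
                                          config$paint$lambda_grid))
  props <- global_proportions(painting)
  segs <- stage("segments", {
    s <- segment_and_test(painting, props,
                          f_min = config$segments$f_min,
                          len_min = config$segments$len_min,
                          alpha = config$segments$alpha)
    wtab(s$retained, "excess_segments.tsv")
    tr <- ancestry_tracts(painting)
    write.table(data.frame(tr$chrom, tr$start_bp, tr$end_bp,
                           sprintf("hap%03d_anc%d", tr$hap, tr$ancestry)),
                file.path(out, "tracts.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    s
  })
  date_fit <- stage("date", {
    cv <- weighted_ld_curve(st, panels$haps[[1]], panels$haps[[2]],
                            cM_per_Mb = cfg$cM_per_Mb,
                            bin_cM = config$dating$bin_cM,
                            max_cM = config$dating$max_cM,
                            min_pairs = config$dating$min_pairs,
                            max_sites = config$dating$max_sites)
    wtab(cv$bins, "wld_curve.tsv")
    f <- tryCatch(fit_decay(cv, d_min_cM = config$dating$d_min_cM),
                  error = function(e) list(A = NA, n_hat = NA, c = NA,
                                           se = NA, flag = "fit_failed"))
    jsonlite::write_json(f[c("A", "n_hat", "c", "se", "bins_used", "flag")],
                         file.path(out, "date_fit.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    f
  })
  scans <- stage("sweep", {
    ihs <- ehh_ihs(st, cM_per_Mb = cfg$cM_per_Mb, win = pw$scan_win)
    clr <- clr_scan(st, win = pw$scan_win)
    wtab(ihs$window, "ihs_windows.tsv"); wtab(clr, "clr_windows.tsv")
    list(ihs = ihs$window, clr = clr)
  })
  inter <- stage("intersect", {
    r <- rank_and_intersect(list(iHS = scans$ihs, CLR = scans$clr,
                                 FST = stats_out$fst, TPR = stats_out$tpr),
                            top_q = config$intersect$top_q,
                            min_methods = config$intersect$min_methods)
    write.table(r$regions, file.path(out, "candidate_regions.bed"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    r
  })
  summary <- list(
    seed = config$seed,
    n_sites = length(st$pos), n_samples = length(st$samples),
    global_proportions = as.list(setNames(as.numeric(props),
                                          names(props))),
    true_proportions = as.numeric(truth$true_prop),
    admixture_generations = date_fit$n_hat,
    admixture_se = date_fit$se,
    n_excess_segments = nrow(segs$retained),
    n_roh = nrow(roh),
    n_candidate_regions = nrow(inter$regions))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(summary)
}
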