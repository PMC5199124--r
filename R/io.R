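#' Write a trace matrix and metadata sidecar
#'
#' Traces are stored as delimited text with one row per cell (first column
#' `cell_id`, remaining columns time points); acquisition metadata (sampling
#' interval, stimulus frame, optional per-cell calibration constants) goes in
#' a JSON sidecar.
#'
#' @param traces Numeric matrix (rows = cells); rownames become cell ids.
#' @param path Output CSV path.
#' @param metadata_path Output JSON path.
#' @param dt Sampling interval (s).
#' @param stim_index 1-based stimulus frame.
#' @param calibration Optional named list of per-cell
#'   `list(kd=, fmin=, fmax=)`.
#' @param truth Optional ground-truth sidecar content (e.g. thetas and regime
#'   labels from the synthetic generator), stored under `truth` in the JSON.
#' @return Invisibly, the two paths.
#' @export
write_traces <- function(traces, path, metadata_path, dt, stim_index,
                         calibration = NULL, truth = NULL) {
  ids <- rownames(traces)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(nrow(traces)))
  lines <- vapply(seq_len(nrow(traces)), function(i)
    paste(c(ids[i], sprintf("%.17g", traces[i, ])), collapse = ","),
    character(1))
  writeLines(lines, path)
  meta <- list(dt = dt, stim_index = stim_index)
  if (!is.null(calibration)) meta$calibration <- calibration
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, metadata_path))
}

#' Read traces and metadata
#'
#' Reads the matrix layout written by [write_traces()]. Rows that fail
#' validation (non-numeric cells, NA values, ragged length) are dropped with
#' a warning naming the row numbers; the remaining cells load.
#'
#' @param path Trace CSV (first column cell id, no header).
#' @param metadata_path JSON sidecar with `dt`, `stim_index`, optional
#'   `calibration`.
#' @return List with `traces` (list of [calcium_trace()]), `bad_rows`
#'   (integer vector), `metadata` (parsed sidecar).
#' @export
read_traces <- function(path, metadata_path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (key in c("dt", "stim_index"))
    if (is.null(meta[[key]]))
      stop("metadata missing required key '", key, "'")
  lines <- readLines(path)
  if (!length(lines)) stop("empty trace file: ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(parts)
  ref_w <- as.numeric(names(which.max(table(widths))))
  traces <- list()
  bad <- integer(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    id <- gsub('^"|"$', "", p[1])
    vals <- suppressWarnings(as.numeric(p[-1]))
    if (length(p) != ref_w || anyNA(vals)) {
      bad <- c(bad, i)
      next
    }
    cal <- NULL
    if (!is.null(meta$calibration) && !is.null(meta$calibration[[id]]))
      cal <- meta$calibration[[id]]
    traces[[id]] <- calcium_trace(vals, dt = meta$dt,
                                  stim_index = meta$stim_index,
                                  cell_id = id, calibration = cal)
  }
  if (length(bad))
    warning("dropped malformed row(s): ", paste(bad, collapse = ", "))
  if (!length(traces)) stop("no valid traces in ", path)
  list(traces = traces, bad_rows = bad, metadata = meta)
}

#' Pipeline configuration
#'
#' @param input,metadata Input trace matrix CSV and JSON sidecar paths.
#' @param outdir Output directory (created if missing).
#' @param atp Stimulus concentration (uM).
#' @param cutoff Low-pass cutoff (Hz).
#' @param score_cfg A [score_config()].
#' @param smc_cfg An [smc_config()].
#' @param k_range Candidate cluster counts.
#' @param seed Master seed; per-cell per-run seeds are derived from it so the
#'   whole run is exactly reproducible.
#' @param alpha Convergence-test significance level.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, metadata, outdir, atp = 10,
                            cutoff = 0.1, score_cfg = score_config(),
                            smc_cfg = smc_config(), k_range = 2:10,
                            seed = 1, alpha = 0.05) {
  structure(list(input = input, metadata = metadata, outdir = outdir,
                 atp = atp, cutoff = cutoff, score_cfg = score_cfg,
                 smc_cfg = smc_cfg, k_range = k_range, seed = seed,
                 alpha = alpha),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' preprocess -> dual-run ABC-SMC fit -> convergence filter -> KL distance
#' matrix -> average-linkage clustering -> mechanistic characterization.
#' Per-cell failures at any stage are recorded in the attrition table, never
#' fatal. All artifacts (ensembles, convergence reports, distance matrix,
#' labels, attrition, config echo) are written to `outdir` as delimited text.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `ensembles`, `convergence`, `dmat`,
#'   `clustering`, `characterization`, `attrition`, `features`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else
    function(...) message(sprintf(...))
  inp <- read_traces(cfg$input, cfg$metadata)
  if (!length(inp$traces)) stop("no input cells")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  n_cells <- length(inp$traces)
  ids <- names(inp$traces)
  set.seed(cfg$seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1, 2 * n_cells),
                     n_cells, 2)
  proto <- stimulus_protocol(atp = cfg$atp, t_on = 0, duration = 1,
                             dt_out = inp$metadata$dt)

  ensembles <- list()
  conv_rows <- list()
  feat_rows <- list()
  attempted <- n_cells
  completed <- 0L
  convergent <- 0L
  for (i in seq_len(n_cells)) {
    tr <- inp$traces[[i]]
    pre <- preprocess_trace(tr, cutoff = cfg$cutoff,
                            score_cfg = cfg$score_cfg)
    fe <- pre$features
    feat_rows[[ids[i]]] <- data.frame(
      cell_id = ids[i], f0 = fe$f0, t50u = fe$t50u, tm = fe$tm, fm = fe$fm,
      t50d = fe$t50d, ff = fe$ff, responder = fe$responder)
    say("fitting %s (eps_final=%.3g) ...", ids[i], pre$epsilon_final)
    runs <- lapply(1:2, function(r)
      fit_cell(pre$processed, pre$epsilon_final, cfg$smc_cfg,
               protocol = proto, score_cfg = cfg$score_cfg, run_id = r,
               seed = seed_tab[i, r]))
    ok <- vapply(runs, `[[`, logical(1), "fitted")
    if (!all(ok)) {
      conv_rows[[ids[i]]] <- data.frame(cell_id = ids[i], fitted = FALSE,
                                        converged = FALSE, p_value = NA,
                                        p_same_run = NA)
      next
    }
    completed <- completed + 1L
    set.seed(seed_tab[i, 1])  # tie-break RNG for the NN test
    rep <- test_convergence(runs[[1]], runs[[2]], alpha = cfg$alpha)
    conv_rows[[ids[i]]] <- data.frame(cell_id = ids[i], fitted = TRUE,
                                      converged = rep$converged,
                                      p_value = rep$p_value,
                                      p_same_run = rep$p_same_run)
    if (rep$converged) {
      convergent <- convergent + 1L
      pooled <- rbind(runs[[1]]$particles, runs[[2]]$particles)
      ens <- runs[[1]]
      ens$particles <- pooled
      ens$scores <- c(runs[[1]]$scores, runs[[2]]$scores)
      ens$run_id <- "pooled"
      ens$cell_id <- ids[i]
      ensembles[[ids[i]]] <- ens
      ens_df <- data.frame(cell_id = ids[i],
                           run_id = rep(c(1L, 2L),
                                        c(nrow(runs[[1]]$particles),
                                          nrow(runs[[2]]$particles))),
                           pooled, score = ens$scores, check.names = FALSE)
      utils::write.csv(ens_df,
                       file.path(cfg$outdir,
                                 paste0("ensemble_", ids[i], ".csv")),
                       row.names = FALSE)
    }
  }
  conv_df <- do.call(rbind, conv_rows)
  feat_df <- do.call(rbind, feat_rows)
  utils::write.csv(conv_df, file.path(cfg$outdir, "convergence.csv"),
                   row.names = FALSE)
  utils::write.csv(feat_df, file.path(cfg$outdir, "features.csv"),
                   row.names = FALSE)

  clustering <- NULL
  characterization <- NULL
  dmat <- NULL
  clustered <- 0L
  if (length(ensembles) >= 3) {
    set.seed(cfg$seed + 1L)
    dmat <- ensemble_distance_matrix(ensembles)
    utils::write.csv(as.data.frame(unclass(dmat)),
                     file.path(cfg$outdir, "distance_matrix.csv"))
    clustering <- cluster_ensembles(dmat, k_range = cfg$k_range)
    characterization <- characterize_clusters(ensembles,
                                              clustering$labels)
    clustered <- length(clustering$labels)
    utils::write.csv(data.frame(cell_id = names(clustering$labels),
                                cluster = as.integer(clustering$labels)),
                     file.path(cfg$outdir, "clusters.csv"),
                     row.names = FALSE)
  }
  attrition <- data.frame(stage = c("attempted", "completed", "convergent",
                                    "clustered"),
                          n_cells = c(attempted, completed, convergent,
                                      clustered))
  utils::write.csv(attrition, file.path(cfg$outdir, "attrition.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, atp = cfg$atp, cutoff = cfg$cutoff,
         n_particles = cfg$smc_cfg$n_particles,
         quantile = cfg$smc_cfg$quantile,
         max_iterations = cfg$smc_cfg$max_iterations,
         k_range = cfg$k_range, alpha = cfg$alpha),
    file.path(cfg$outdir, "config.json"), auto_unbox = TRUE)
  say("attrition: %s", paste(attrition$stage, attrition$n_cells,
                             sep = "=", collapse = ", "))
  invisible(list(ensembles = ensembles, convergence = conv_df, dmat = dmat,
                 clustering = clustering,
                 characterization = characterization,
                 attrition = attrition, features = feat_df))
}
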