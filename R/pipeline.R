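# Orchestration: synthetic-or-file ingest -> kriging -> clr -> robust PFA
# -> per-endpoint BYM fits -> association report, with deterministic
# per-stage seeds and hash-stamped outputs.

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "geomort-run",
    endpoints = list(list(site = "siteA", beta = c(0.15, 0, 0, 0))),
    synthetic = list(n_points = 400, bbox = c(0, 0, 10, 10), nx = 15, ny = 15,
                     field = list(), truth = list(alpha = 0, delta = rep(0, 7),
                                                  tau_u = 10, tau_v = 10),
                     expected_range = c(20, 200)),
    files = NULL,
    kriging = list(n_bins = 15, max_dist = NULL, family = "exponential",
                   neighborhood = 32),
    factors = list(k = 4, mcd_fraction = 0.75),
    regression = list(chains = 2, iter = 4000, burnin = 2000, thin = 5)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list; unspecified entries fall back
#' to package defaults. A configuration must name at least one endpoint
#' (cancer site; both sexes are analysed per endpoint) and either a
#' `synthetic` block or a `files` block with paths to the sample, area and
#' adjacency CSVs.
#'
#' @param config YAML path or named list.
#' @return validated config list (class `run_config`) with `hash`, an MD5
#'   of the canonical JSON serialisation.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_config(default_config(), config)
  if (length(cfg$endpoints) == 0)
    stop("config validation error: endpoints list is empty")
  for (ep in cfg$endpoints)
    if (is.null(ep$site)) stop("config validation error: endpoint without a site name")
  if (is.null(cfg$synthetic) && is.null(cfg$files))
    stop("config validation error: need a synthetic block or input file paths")
  if (!is.null(cfg$files))
    for (f in unlist(cfg$files))
      if (!file.exists(f)) stop("config validation error: missing input file ", f)
  cfg$seed <- as.integer(cfg$seed)
  # hash the analytic content only: the output location must not change it
  hashed <- cfg[setdiff(names(cfg), "output_dir")]
  json <- jsonlite::toJSON(hashed, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(); writeLines(json, tmp)
  cfg$hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  class(cfg) <- "run_config"
  cfg
}

# CSV with a config-hash stamp as a comment line; read back with
# comment.char = "#".
write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Write a synthetic sample-point set to CSV
#'
#' Columns: `x`, `y`, then one column per element (mg/kg).
#'
#' @param sp a `sample_points` object.
#' @param path output CSV path.
#' @param hash optional config hash stamped as a leading comment.
#' @export
write_sample_points <- function(sp, path, hash = "none") {
  write_csv_hashed(data.frame(sp$coords, sp$concentrations, check.names = FALSE),
                   path, hash)
  invisible(path)
}

#' Write an area table and its adjacency to CSV
#'
#' The area CSV carries `area_id`, centroid coordinates and any count or
#' covariate columns; the adjacency is a two-column undirected edge list
#' (each edge once).
#'
#' @param at an `area_table`.
#' @param area_path,adjacency_path output CSV paths.
#' @param hash optional config hash stamp.
#' @export
write_area_table <- function(at, area_path, adjacency_path, hash = "none") {
  write_csv_hashed(at$areas, area_path, hash)
  write_csv_hashed(as.data.frame(at$edges), adjacency_path, hash)
  invisible(c(area_path, adjacency_path))
}

#' Read an area table written by [write_area_table()]
#'
#' @param area_path,adjacency_path CSV paths.
#' @return an `area_table`.
#' @export
read_area_table <- function(area_path, adjacency_path) {
  areas <- utils::read.csv(area_path, comment.char = "#")
  edges <- as.matrix(utils::read.csv(adjacency_path, comment.char = "#"))
  n <- nrow(areas)
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
  }
  nbrs <- lapply(nbrs, function(v) sort(unique(as.integer(v))))
  structure(list(areas = areas, neighbors = nbrs, edges = edges),
            class = "area_table")
}

# deterministic per-endpoint/sex seed derived from the global seed
endpoint_seed <- function(seed, endpoint_index, sex_index) {
  (seed * 2011L + endpoint_index * 101L + sex_index * 13L) %% 2147483L + 1L
}

#' Build the association report from per-endpoint fits
#'
#' One row per endpoint x factor x sex with RR, 95% credibility interval
#' and significance (interval excludes 1). `shared_flag` marks endpoint x
#' factor cells significant in both sexes with RR on the same side of 1 —
#' the "shared by men and women" convention of ecological cancer-mapping
#' reports.
#'
#' @param fits nested list: `fits[[site]][[sex]]` is a `bym_fit`.
#' @param factor_names names of the factor-score covariates.
#' @return data.frame of class `association_report`.
#' @export
association_report <- function(fits, factor_names) {
  rows <- list()
  for (site in names(fits)) for (sex in names(fits[[site]])) {
    rr <- fits[[site]][[sex]]$summary$rr
    rr <- rr[rr$parameter %in% factor_names, ]
    rows[[length(rows) + 1]] <- data.frame(
      site = site, factor = rr$parameter, sex = sex,
      RR = rr$RR, ci_low = rr$ci_low, ci_high = rr$ci_high,
      significant = rr$significant)
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  rep$shared_flag <- FALSE
  for (site in unique(rep$site)) for (f in unique(rep$factor)) {
    sel <- rep$site == site & rep$factor == f
    if (sum(sel) < 2) next
    sig <- rep$significant[sel]
    side <- sign(rep$RR[sel] - 1)
    if (all(sig) && length(unique(side)) == 1 && side[1] != 0)
      rep$shared_flag[sel] <- TRUE
  }
  class(rep) <- c("association_report", "data.frame")
  rep
}

#' Run the full ecological-regression pipeline
#'
#' Executes ingest (synthetic generation or CSV input), per-element
#' ordinary kriging to area centroids, clr transformation, robust PFA with
#' varimax rotation and sign-aligned scores, one BYM fit per endpoint and
#' sex, and the association report. All stage outputs are written under
#' `config$output_dir`, each stamped with the config hash, along with a
#' structured JSON log of stage parameters and seeds. Per-endpoint fits
#' run sequentially with seeds derived deterministically from the global
#' seed, so a rerun with the same config is byte-identical.
#'
#' In synthetic mode each endpoint is simulated for both sexes from the
#' configured ground-truth effects (the endpoint's `beta` applies to both
#' sexes); in file mode the area CSV must carry `obs_<site>_<sex>` /
#' `exp_<site>_<sex>` count columns.
#'
#' @param config YAML path or named list (see [load_run_config()]).
#' @return (invisibly) list with `config`, `report`, `fits`, `factors`
#'   (model + scores), `kriged`, `output_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config_hash = cfg$hash, seed = cfg$seed, stages = list())
  stage <- function(name, params)
    log$stages[[length(log$stages) + 1]] <<- c(list(stage = name), params)

  # --- ingest ------------------------------------------------------------
  synth <- !is.null(cfg$synthetic) && is.null(cfg$files)
  if (synth) {
    sy <- cfg$synthetic
    fld <- do.call(field_params, c(sy$field, list(seed = cfg$seed)))
    sp <- tryCatch(
      generate_sample_points(sy$n_points, bbox = sy$bbox, field = fld),
      error = function(e) stop("stage ingest failed: ", conditionMessage(e)))
    lattice <- generate_area_lattice(sy$nx, sy$ny)
    # scale lattice centroids into the sampling bbox
    lattice$areas$x <- sy$bbox[1] + (lattice$areas$x / sy$nx) * (sy$bbox[3] - sy$bbox[1])
    lattice$areas$y <- sy$bbox[2] + (lattice$areas$y / sy$ny) * (sy$bbox[4] - sy$bbox[2])
    stage("ingest", list(mode = "synthetic", n_points = sy$n_points,
                         nx = sy$nx, ny = sy$ny, seed = cfg$seed))
    write_sample_points(sp, file.path(cfg$output_dir, "sample_points.csv"), cfg$hash)
  } else {
    sam <- utils::read.csv(cfg$files$samples, comment.char = "#")
    sp <- structure(list(coords = as.matrix(sam[, c("x", "y")]),
                         concentrations = as.matrix(sam[, setdiff(names(sam), c("x", "y"))])),
                    class = "sample_points")
    lattice <- read_area_table(cfg$files$areas, cfg$files$adjacency)
    stage("ingest", list(mode = "files", samples = cfg$files$samples))
  }
  centroids <- as.matrix(lattice$areas[, c("x", "y")])

  # --- kriging -----------------------------------------------------------
  kr <- tryCatch(
    krige_composition(sp, centroids, n_bins = cfg$kriging$n_bins,
                      max_dist = cfg$kriging$max_dist,
                      family = cfg$kriging$family,
                      neighborhood = cfg$kriging$neighborhood),
    error = function(e) stop("stage kriging failed: ", conditionMessage(e)))
  stage("kriging", cfg$kriging)
  write_csv_hashed(data.frame(area_id = lattice$areas$area_id, kr$predictions,
                              check.names = FALSE),
                   file.path(cfg$output_dir, "kriged_composition.csv"), cfg$hash)
  jsonlite::write_json(
    lapply(kr$variograms, function(v) v[c("family", "nugget", "partial_sill", "range")]),
    file.path(cfg$output_dir, "variograms.json"), auto_unbox = TRUE, digits = NA)
  write_csv_hashed(kr$range_report,
                   file.path(cfg$output_dir, "range_report.csv"), cfg$hash)

  # --- clr + factor analysis ---------------------------------------------
  y <- clr_transform(kr$predictions)
  write_csv_hashed(data.frame(area_id = lattice$areas$area_id, y,
                              check.names = FALSE),
                   file.path(cfg$output_dir, "clr.csv"), cfg$hash)
  fa <- tryCatch(
    robust_pfa(y, k = cfg$factors$k, mcd_fraction = cfg$factors$mcd_fraction,
               seed = cfg$seed),
    error = function(e) stop("stage factor_analysis failed: ", conditionMessage(e)))
  stage("factor_analysis", c(cfg$factors,
                             list(cumulative_share = fa$model$cumulative_share)))
  factor_names <- colnames(fa$model$loadings)
  write_csv_hashed(data.frame(element = rownames(fa$model$loadings),
                              fa$model$loadings,
                              communality = fa$model$communalities,
                              check.names = FALSE),
                   file.path(cfg$output_dir, "loadings.csv"), cfg$hash)
  # long-format loading-plot data (element, factor, loading)
  ld <- as.data.frame(as.table(fa$model$loadings))
  names(ld) <- c("element", "factor", "loading")
  write_csv_hashed(ld, file.path(cfg$output_dir, "loading_plot_data.csv"), cfg$hash)
  write_csv_hashed(data.frame(area_id = lattice$areas$area_id, fa$scores,
                              check.names = FALSE),
                   file.path(cfg$output_dir, "scores.csv"), cfg$hash)

  # --- per-endpoint BYM fits ----------------------------------------------
  structure_ <- build_icar(lattice)
  sexes <- c("men", "women")
  fits <- list()
  soc <- NULL
  for (ei in seq_along(cfg$endpoints)) {
    ep <- cfg$endpoints[[ei]]
    fits[[ep$site]] <- list()
    for (si in seq_along(sexes)) {
      sx <- sexes[si]
      sd_seed <- endpoint_seed(cfg$seed, ei, si)
      if (synth) {
        tr <- do.call(truth_params, c(
          cfg$synthetic$truth,
          list(beta = as.numeric(ep$beta), seed = sd_seed)))
        if (is.null(soc)) soc <- generate_soc_covariates(nrow(lattice$areas),
                                                         seed = cfg$seed)
        at <- simulate_mortality(lattice, fa$scores[, seq_along(tr$beta), drop = FALSE],
                                 truth = tr,
                                 expected_range = cfg$synthetic$expected_range,
                                 soc = soc, seed = sd_seed)
      } else {
        at <- lattice
        oc <- paste0("obs_", ep$site, "_", sx)
        ec <- paste0("exp_", ep$site, "_", sx)
        if (!all(c(oc, ec) %in% names(at$areas)))
          stop("stage regression failed: missing count columns ", oc, "/", ec)
        at$areas$observed <- at$areas[[oc]]
        at$areas$expected <- at$areas[[ec]]
        at$soc_names <- intersect(names(generate_soc_covariates(1)), names(at$areas))
      }
      covn <- c(factor_names, at$soc_names)
      rs <- regression_spec(covn,
                            chains = cfg$regression$chains,
                            iter = cfg$regression$iter,
                            burnin = cfg$regression$burnin,
                            thin = cfg$regression$thin,
                            seed = sd_seed)
      fit <- tryCatch(
        fit_bym(rs, structure_, at, fa$scores),
        error = function(e) stop("stage regression failed at endpoint ",
                                 ep$site, "/", sx, ": ", conditionMessage(e)))
      fits[[ep$site]][[sx]] <- fit
      stage("regression", list(site = ep$site, sex = sx, seed = sd_seed,
                               converged = fit$summary$converged))
      write_csv_hashed(fit$summary$rr,
                       file.path(cfg$output_dir,
                                 paste0("fit_", ep$site, "_", sx, ".csv")),
                       cfg$hash)
    }
  }

  # --- report --------------------------------------------------------------
  rep <- association_report(fits, factor_names)
  write_csv_hashed(rep, file.path(cfg$output_dir, "report.csv"), cfg$hash)
  write_csv_hashed(rep[rep$RR > 1, ], file.path(cfg$output_dir, "report_rr_gt1.csv"),
                   cfg$hash)
  write_csv_hashed(rep[rep$RR < 1, ], file.path(cfg$output_dir, "report_rr_lt1.csv"),
                   cfg$hash)
  # factor-score map file (choropleth-ready), with posterior u of the first fit
  u_mean <- fits[[1]][[1]]$summary$u
  write_csv_hashed(data.frame(area_id = lattice$areas$area_id,
                              x = lattice$areas$x, y = lattice$areas$y,
                              fa$scores, u_posterior_mean = u_mean,
                              check.names = FALSE),
                   file.path(cfg$output_dir, "score_map.csv"), cfg$hash)
  if (synth)
    write_area_table(lattice, file.path(cfg$output_dir, "areas.csv"),
                     file.path(cfg$output_dir, "adjacency.csv"), cfg$hash)
  cfg_echo <- unclass(cfg)
  jsonlite::write_json(cfg_echo, file.path(cfg$output_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  jsonlite::write_json(log, file.path(cfg$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(config = cfg, report = rep, fits = fits,
                 factors = fa, kriged = kr, output_dir = cfg$output_dir))
}
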