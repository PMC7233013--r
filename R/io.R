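#' Read and write peak lists as TSV
#'
#' Peak lists are tab-separated with columns \code{fs}, \code{ss},
#' \code{intensity}, \code{snr} (plus any extra columns, e.g. simulation
#' truth). The header line is optional on input: a first line of numeric
#' tokens is treated as data in the canonical column order. Malformed rows
#' raise an error naming the offending line; an empty list is valid but
#' flagged with a message.
#'
#' @param path file path.
#' @return \code{read_peaks}: a \code{\link{peak_list}} in file order.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    message("empty peak list: ", path)
    return(peak_list(numeric(), numeric()))
  }
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  if (has_header) {
    cols <- first
    body <- lines[-1L]
    off <- 1L
  } else {
    cols <- c("fs", "ss", "intensity", "snr")[seq_along(first)]
    body <- lines
    off <- 0L
  }
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    message("empty peak list: ", path)
    return(peak_list(numeric(), numeric()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols)))
    stop("malformed peak row at line ",
         which(nf != length(cols))[1L] + off, " of ", path)
  vals <- suppressWarnings(
    lapply(seq_along(cols), function(k)
      as.numeric(vapply(parts, `[[`, "", k))))
  bad <- which(Reduce(`|`, lapply(vals, is.na)))
  # logical truth columns come back NA from as.numeric; retry those as logical
  for (k in seq_along(cols)) {
    if (anyNA(vals[[k]])) {
      lv <- as.logical(vapply(parts, `[[`, "", k))
      if (!anyNA(lv)) vals[[k]] <- lv
    }
  }
  bad <- which(Reduce(`|`, lapply(vals, function(v) is.na(v))))
  if (length(bad))
    stop("malformed peak row at line ", bad[1L] + off, " of ", path)
  df <- as.data.frame(stats::setNames(vals, cols))
  if (!all(c("fs", "ss") %in% names(df)))
    stop("peak file must provide fs and ss columns: ", path)
  if (is.null(df$intensity)) df$intensity <- 1
  if (is.null(df$snr)) df$snr <- 1
  class(df) <- c("peak_list", "data.frame")
  df
}

#' @rdname read_peaks
#' @param peaks a \code{\link{peak_list}} or compatible data frame.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

.config_defaults <- function() list(
  cell_a = 64.3, cell_b = 72.0, cell_c = 89.2,
  cell_alpha = 110.6, cell_beta = 107.5, cell_gamma = 85.8,
  n_fast = 1440L, n_slow = 1440L,
  pixel_size_m = 100e-6, distance_m = 0.1,
  beam_center_fs = 719.5, beam_center_ss = 719.5,
  energy_1_kev = 7, energy_2_kev = 9,
  delta = 0.25, n_pairs = 5L, sort_key = "snr",
  tol_len_inv_angstrom = 0.0025, tol_angle_deg = 1.0,
  table_d_min_angstrom = 5.0, min_angle_sep_deg = 10.0,
  sim_d_min_angstrom = 3.0, sphere_radius_inv_angstrom = 0.0015,
  pixel_jitter_px = 0.0, n_patterns = 100L, seed = 1L)

#' Run configuration
#'
#' Flat key-value configuration tying the whole pipeline together; units are
#' spelled out in the key names. Unknown keys are rejected, and
#' parse -> serialize -> parse is lossless.
#'
#' @param ... overrides of the default keys (see
#'   \code{tcindex:::.config_defaults()}).
#' @return Named list of class \code{"run_config"}.
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# constructors of domain objects from a run configuration
config_cell <- function(cfg)
  unit_cell(cfg$cell_a, cfg$cell_b, cfg$cell_c,
            cfg$cell_alpha, cfg$cell_beta, cfg$cell_gamma)
config_geometry <- function(cfg)
  detector_geometry(cfg$n_fast, cfg$n_slow, cfg$pixel_size_m, cfg$distance_m,
                    c(cfg$beam_center_fs, cfg$beam_center_ss))
config_beam <- function(cfg) beam_setup(c(cfg$energy_1_kev, cfg$energy_2_kev))
config_params <- function(cfg)
  indexer_params(delta = cfg$delta, n_pairs = cfg$n_pairs,
                 sort_key = cfg$sort_key,
                 tol_len = cfg$tol_len_inv_angstrom,
                 tol_angle = cfg$tol_angle_deg)
config_simulation <- function(cfg)
  simulation_config(cell = config_cell(cfg), geometry = config_geometry(cfg),
                    beam = config_beam(cfg),
                    sphere_radius = cfg$sphere_radius_inv_angstrom,
                    d_min = cfg$sim_d_min_angstrom,
                    pixel_jitter = cfg$pixel_jitter_px,
                    n_patterns = cfg$n_patterns)

# ---- solutions ------------------------------------------------------------

#' Write / read per-pattern indexing solutions as TSV
#'
#' One row per pattern: id, two-colour score, the 9 row-major elements of U,
#' the 9 row-major elements of A = U B (the oriented reciprocal basis,
#' astar/bstar/cstar semantics), group sizes and the seed pair.
#'
#' @param solutions list of \code{\link{index_two_color}} results
#'   (\code{NULL} entries allowed for unindexed patterns).
#' @param ids pattern identifiers (default sequence).
#' @param path file path.
#' @export
write_solutions <- function(solutions, path, ids = seq_along(solutions)) {
  rows <- lapply(seq_along(solutions), function(i) {
    s <- solutions[[i]]
    if (is.null(s)) {
      v <- c(score = 0, setNames(rep(NA_real_, 18L),
                                 c(paste0("u", 1:9), paste0("a", 1:9))),
             n_color1 = 0, n_color2 = 0, seed_i = NA, seed_j = NA)
    } else {
      A <- s$rotation %*% s$cell$B
      v <- c(score = s$score,
             setNames(as.numeric(t(s$rotation)), paste0("u", 1:9)),
             setNames(as.numeric(t(A)), paste0("a", 1:9)),
             n_color1 = length(s$group_1), n_color2 = length(s$group_2),
             seed_i = s$seed_pair[1L], seed_j = s$seed_pair[2L])
    }
    data.frame(pattern_id = ids[i], t(v))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_solutions
#' @export
read_solutions <- function(path) utils::read.delim(path)

#' Write the per-peak colour classification of a solution
#'
#' @param solution a \code{tc_solution}.
#' @param path file path.
#' @export
write_assignments <- function(solution, path) {
  utils::write.table(solution$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report a \code{\link{evaluate_dataset}} result.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  keep <- c("n_total", "n_indexed", "indexing_rate", "n_correct",
            "correct_threshold", "median_total_error", "median_euler_error",
            "frac_euler_above_0.2", "color_accuracy", "n_color_checked",
            "n_dual_excitable", "mean_peaks_per_pattern")
  jsonlite::write_json(unclass(report)[keep], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
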