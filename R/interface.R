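## Readers, writers and result serialisation. Units are encoded in column
## names (time_min, product_nM, conc_nM, rate_per_min); no unit inference.

.parse_header_meta <- function(lines) {
  meta <- list()
  i <- 0L
  while (i < length(lines) && grepl("^#", lines[i + 1L])) {
    i <- i + 1L
    m <- regmatches(lines[i],
                    regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  list(meta = meta, skip = i)
}

.meta_num <- function(meta, key) {
  v <- meta[[key]]
  if (is.null(v)) return(NA_real_)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop("metadata field ", key, " is not numeric: ", v)
  x
}

#' Read a progress curve from CSV
#'
#' Expected layout: optional `# key: value` comment header (recognised keys:
#' `e_nominal_nM`, `s_total_nM`, `condition`), then a header line containing
#' `time_min,product_nM` with optional replicate columns `product_nM_2`,
#' `product_nM_3`, ... Parse errors name the offending line.
#'
#' @param path CSV file path.
#' @return A [progress_curve()]; replicate columns are kept and averaged into
#'   `product`.
#' @export
read_progress_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hm <- .parse_header_meta(lines)
  body <- lines[(hm$skip + 1L):length(lines)]
  if (!length(body) || !grepl("time_min", body[1])) {
    stop("missing header: expected 'time_min,product_nM' on line ",
         hm$skip + 1L, " of ", path)
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  if (!"time_min" %in% names(df) || !"product_nM" %in% names(df)) {
    stop("missing required columns time_min, product_nM in ", path)
  }
  rep_cols <- grep("^product_nM(_[0-9]+)?$", names(df), value = TRUE)
  tms <- df$time_min
  bad <- which(diff(tms) <= 0)
  if (length(bad)) {
    stop("times out of order at data line ", bad[1] + 1L,
         " (file line ", hm$skip + 1L + bad[1] + 1L, ") of ", path)
  }
  vals <- as.matrix(df[rep_cols])
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative product value at data line ", neg[1, 1] + 1L,
         " (file line ", hm$skip + 1L + neg[1, 1] + 1L, ") of ", path)
  }
  cond <- hm$meta$condition
  progress_curve(
    times = tms,
    replicates = vals,
    e_nominal = .meta_num(hm$meta, "e_nominal_nM"),
    s_total = .meta_num(hm$meta, "s_total_nM"),
    condition = if (is.null(cond)) list() else list(condition = cond))
}

#' Write a progress curve to CSV
#'
#' Inverse of [read_progress_csv()]; metadata goes into `#` header comments,
#' replicates into `product_nM`, `product_nM_2`, ... Values round-trip at
#' full double precision.
#'
#' @param curve A [progress_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_progress_csv <- function(curve, path) {
  stopifnot(inherits(curve, "progress_curve"))
  meta <- character()
  if (is.finite(curve$e_nominal)) {
    meta <- c(meta, sprintf("# e_nominal_nM: %.15g", curve$e_nominal))
  }
  if (is.finite(curve$s_total)) {
    meta <- c(meta, sprintf("# s_total_nM: %.15g", curve$s_total))
  }
  if (length(curve$condition)) {
    meta <- c(meta, paste0("# condition: ",
                           paste(names(curve$condition), curve$condition,
                                 sep = "=", collapse = ";")))
  }
  vals <- if (!is.null(curve$replicates)) curve$replicates
          else matrix(curve$product, ncol = 1L)
  cols <- c("product_nM",
            if (ncol(vals) > 1L) paste0("product_nM_", 2:ncol(vals)))
  header <- paste(c("time_min", cols), collapse = ",")
  rows <- apply(cbind(curve$times, vals), 1L,
                function(r) paste(sprintf("%.15g", r), collapse = ","))
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Read a titration series from CSV
#'
#' Columns: `conc_nM`, `rate_per_min`; optional `# label: ...` header.
#'
#' @param path CSV file path.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hm <- .parse_header_meta(lines)
  df <- utils::read.csv(text = paste(lines[(hm$skip + 1L):length(lines)],
                                     collapse = "\n"))
  if (!all(c("conc_nM", "rate_per_min") %in% names(df))) {
    stop("missing required columns conc_nM, rate_per_min in ", path)
  }
  lbl <- hm$meta$label
  titration_series(df$conc_nM, df$rate_per_min,
                   labels = if (is.null(lbl)) character() else lbl)
}

#' Write a titration series to CSV
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  meta <- if (length(series$labels)) {
    paste0("# label: ", paste(series$labels, collapse = ";"))
  } else character()
  rows <- sprintf("%.15g,%.15g", series$concs, series$k_burst_obs)
  writeLines(c(meta, "conc_nM,rate_per_min", rows), path)
  invisible(path)
}

#' Read RNA sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readBStringSet`; DNA-style T is converted
#' to U and sequences are upper-cased.
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences (5'->3').
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(gsub("T", "U", as.character(ss), ignore.case = TRUE))
  stats::setNames(out, names(ss))
}

#' Write RNA sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

## md5 of the canonical JSON encoding of a config list (base R only)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

## assemble a result record with provenance and write it as JSON
.write_result_json <- function(result, path, config = list(), seed = NULL) {
  rec <- c(result,
           list(meta = list(
             package = "burstfit",
             version = as.character(utils::packageVersion("burstfit")),
             seed = seed,
             config = config,
             config_md5 = .config_hash(config))))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialise a burst fit as a JSON record
#' @param fit A [fit_burst()] result.
#' @param path Output JSON path.
#' @param config Optional config list embedded (and hashed) for provenance.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_burst_fit_json <- function(fit, path, config = list(), seed = NULL) {
  stopifnot(inherits(fit, "burst_fit"))
  ci <- if (!is.null(fit$ci)) {
    apply(fit$ci, 1L, function(r) list(lower = r[[1]], upper = r[[2]]),
          simplify = FALSE)
  }
  .write_result_json(list(
    model = "burst_and_steady_state",
    e_apparent_nM = fit$params$e_active,
    k2_per_min = fit$params$rates$k2,
    k3_per_min = fit$params$rates$k3,
    k_burst_per_min = fit$k_burst,
    k_ss_per_min = fit$k_ss,
    ssr_nM2 = fit$ssr,
    converged = fit$converged,
    n_points = fit$n_points,
    ci = ci,
    ci_method = if (!is.null(ci))
      paste0("bootstrap_percentile_", fit$opts$n_boot)),
    path, config, seed)
}

#' Serialise a titration fit as a JSON record
#' @param fit A [fit_titration()] result.
#' @param path Output JSON path.
#' @param config,seed Provenance (see [write_burst_fit_json()]).
#' @return `path`, invisibly.
#' @export
write_titration_fit_json <- function(fit, path, config = list(),
                                     seed = NULL) {
  stopifnot(inherits(fit, "titration_fit"))
  ci <- if (!is.null(fit$ci)) {
    apply(fit$ci, 1L, function(r) list(lower = r[[1]], upper = r[[2]]),
          simplify = FALSE)
  }
  .write_result_json(list(
    model = "hyperbolic_activation",
    k_pot_per_min = fit$params$k_pot,
    kd_nM = fit$params$kd,
    k0_per_min = fit$k0,
    ssr = fit$ssr,
    converged = fit$converged,
    n_points = fit$n_points,
    ci = ci,
    ci_method = if (!is.null(ci))
      paste0("bootstrap_percentile_", fit$opts$n_boot)),
    path, config, seed)
}
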