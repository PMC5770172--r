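#' Read and validate a biomarker table from CSV
#'
#' Requires the seven biomarker columns
#' `APD20, APD50, APD90, APA, RMP, V20, dVdtmax`; extra columns are dropped
#' with a warning. Rows violating the biomarker invariants
#' (`0 < APD20 <= APD50 <= APD90`, `APA > 0`, `dVdtmax > 0`,
#' `V20 <= RMP + APA`) are rejected with per-row diagnostics.
#'
#' @param path CSV file path (comma-separated, `.` decimal, header row).
#' @param group_label Optional label attached as an attribute.
#' @return Validated data frame of biomarker rows.
#' @export
read_biomarker_table <- function(path, group_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.csv(path, check.names = FALSE)
  missing <- setdiff(BIOMARKER_NAMES, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(x), BIOMARKER_NAMES)
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  x <- x[, BIOMARKER_NAMES]
  for (nm in BIOMARKER_NAMES) {
    if (!is.numeric(x[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[nm]]))))[1]
      stop("non-numeric value in column ", nm, " at row ", bad)
    }
  }
  ok <- validate_biomarker_rows(x)
  if (any(!ok))
    warning(sum(!ok), " row(s) rejected for violating biomarker invariants: ",
            paste(utils::head(which(!ok), 10), collapse = ", "),
            if (sum(!ok) > 10) ", ..." else "", call. = FALSE)
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 valid rows remain")
  rownames(x) <- NULL
  attr(x, "group_label") <- group_label
  x
}

validate_biomarker_rows <- function(x) {
  with(x, is.finite(APD20) & is.finite(APD50) & is.finite(APD90) &
         is.finite(APA) & is.finite(RMP) & is.finite(V20) &
         is.finite(dVdtmax) &
         APD20 > 0 & APD20 <= APD50 & APD50 <= APD90 &
         APA > 0 & dVdtmax > 0 & V20 <= RMP + APA)
}

fmt_full <- function(v) sprintf("%.17g", v)

#' Write a population of models to CSV
#'
#' One row per member: parameter columns then biomarker columns, at full
#' floating-point precision, preceded by `#`-prefixed provenance comment
#' lines (method, seed, calibration settings) so a population file is
#' self-describing.
#'
#' @param x A [pom()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population <- function(x, path) {
  stopifnot(inherits(x, "pom"))
  prov <- vapply(names(x$provenance), function(k)
    sprintf("# %s: %s", k,
            paste(format(x$provenance[[k]], digits = 10), collapse = " ")),
    character(1))
  header <- paste(c(sprintf("# pomcal population; %d theta column(s), %d biomarker column(s)",
                            ncol(x$theta), ncol(x$biomarkers)),
                    prov), collapse = "\n")
  df <- cbind(x$theta, x$biomarkers)
  lines <- c(header,
             paste(colnames(df), collapse = ","),
             apply(df, 1, function(r) paste(fmt_full(r), collapse = ",")))
  if (nrow(df) == 0) lines <- lines[1:2]
  writeLines(lines, path)
  invisible(path)
}

#' Read a population of models from CSV
#'
#' @param path A file written by [write_population()].
#' @return A [pom()]; provenance holds the parsed comment header.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  all_lines <- readLines(path)
  comments <- all_lines[startsWith(all_lines, "#")]
  m <- regmatches(comments[1],
                  regexec("(\\d+) theta column\\(s\\), (\\d+) biomarker", comments[1]))[[1]]
  if (length(m) != 3)
    stop("not a population file (missing layout header): ", path)
  n_theta <- as.integer(m[2]); n_bio <- as.integer(m[3])
  df <- read.csv(text = all_lines[!startsWith(all_lines, "#")],
                 check.names = FALSE)
  if (ncol(df) != n_theta + n_bio)
    stop("column layout mismatch: header declares ", n_theta + n_bio,
         " columns, file has ", ncol(df))
  prov <- list()
  for (cm in comments[-1]) {
    kv <- regmatches(cm, regexec("^# ([^:]+): (.*)$", cm))[[1]]
    if (length(kv) == 3) prov[[kv[2]]] <- kv[3]
  }
  pom(as.matrix(df[, seq_len(n_theta), drop = FALSE]),
      as.matrix(df[, n_theta + seq_len(n_bio), drop = FALSE]),
      provenance = prov)
}

#' Write / read an AP trace as CSV
#'
#' Columns `t_ms,V_mV`.
#'
#' @param trace An [ap_trace()].
#' @param path File path.
#' @return `path` invisibly, or the re-read `ap_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ap_trace"))
  df <- data.frame(t_ms = fmt_full(trace$t), V_mV = fmt_full(trace$V))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  if (!all(c("t_ms", "V_mV") %in% names(df)))
    stop("trace CSV must have columns t_ms,V_mV")
  ap_trace(df$t_ms, df$V_mV)
}

#' Serialise / restore a fitted density estimate as JSON
#'
#' Portable representation of a [fit_density()] object: transformed data
#' points, the bandwidth diagonal, the transform spec and the convention.
#'
#' @param est A `biomarker_kde`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `biomarker_kde`.
#' @export
write_density <- function(est, path) {
  stopifnot(inherits(est, "biomarker_kde"))
  obj <- list(points = est$points, H = as.list(est$H),
              h_opt = est$h_opt, transform = as.list(est$transform),
              sigma2 = as.list(est$sigma2), convention = est$convention,
              group_label = est$group_label)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- as.matrix(obj$points)
  structure(list(points = pts, H = unlist(obj$H), h_opt = obj$h_opt,
                 transform = unlist(obj$transform),
                 sigma2 = unlist(obj$sigma2), convention = obj$convention,
                 group_label = obj$group_label),
            class = "biomarker_kde")
}

run_config_keys <- c(
  "protocol", "bounds", "smc", "refine", "density", "seed")

#' Read a run configuration from YAML or JSON
#'
#' Recognised top-level keys: `protocol` (fields of
#' [stimulus_protocol()]), `bounds` (`lower`, `upper`, `gNa_upper`,
#' `include_tau_h`), `smc` (`N`, `ess_frac`, `G_max`), `refine` (fields of
#' [refinement_config()] plus `mode`, `n_bins`), `density` (`transform`,
#' `bandwidth_convention`) and `seed`. Unknown keys are rejected.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), run_config_keys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg
}

# small stable config fingerprint for run logs (polynomial rolling hash of
# the serialised configuration)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
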