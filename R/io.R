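#' Read a plasma assay table
#'
#' Expects a delimited text file with header columns `subject_id`, `group`,
#' `health_state`, `mmtt`, `time_min`, `fagbh`, `fagah` (case-insensitive;
#' readings in µg/mL amine-group equivalents). `fagbh`/`fagah` are returned as
#' `F`/`T`. Malformed rows (non-numeric or non-positive readings) are dropped
#' with a warning naming the line numbers.
#'
#' @param path file path.
#' @param sep field delimiter (default comma).
#' @return validated data.frame with columns `subject_id`, `group`,
#'   `health_state`, `mmtt`, `time_min`, `F`, `T`.
#' @export
read_assay_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  names(raw) <- tolower(names(raw))
  req <- c("subject_id", "group", "health_state", "mmtt", "time_min",
           "fagbh", "fagah")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  f <- suppressWarnings(as.numeric(raw$fagbh))
  t <- suppressWarnings(as.numeric(raw$fagah))
  tm <- suppressWarnings(as.numeric(raw$time_min))
  bad <- !is.finite(f) | !is.finite(t) | !is.finite(tm) | f <= 0 | t <= 0
  if (any(bad))
    warning("dropped ", sum(bad), " malformed row(s) (line ",
            paste(which(bad) + 1L, collapse = ", "),
            "): readings must be numeric and positive", call. = FALSE)
  data.frame(subject_id = as.character(raw$subject_id),
             group = as.character(raw$group),
             health_state = as.character(raw$health_state),
             mmtt = as.character(raw$mmtt),
             time_min = tm, F = f, T = t,
             stringsAsFactors = FALSE)[!bad, , drop = FALSE]
}

# deterministic multiply mod 2^32 without integer overflow
.mul32 <- function(a, b) {
  lo <- (a %% 65536) * b
  hi <- ((a %/% 65536) * b) %% 65536
  (lo + hi * 65536) %% 4294967296
}

# FNV-1a 32-bit fingerprint of a deparsed object (xor only touches the low
# byte since input bytes are < 256; doubles hold exact 32-bit values)
.config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- .mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write an output table with a provenance header
#'
#' Writes a delimited table prefixed with `#`-comment metadata lines
#' (software version, config fingerprint, seed), numeric columns at fixed
#' precision so identical runs are byte-identical.
#'
#' @param table data.frame to write.
#' @param path destination.
#' @param config optional configuration object recorded in the header.
#' @param seed optional seed recorded in the header.
#' @param digits decimal places for numeric columns.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(table, path, config = NULL, seed = NULL,
                               digits = 6, sep = ",") {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                 format = "f"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# pepstruct ", as.character(utils::packageVersion("pepstruct"))),
    paste0("# config_hash: ",
           if (is.null(config)) "none" else .config_hash(config)),
    paste0("# seed: ", if (is.null(seed)) "none" else seed)
  ), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Recognised keys (all optional): `method`, `grid_resolution`, `mc_samples`,
#' `seed`, `alpha_max`, `beta_max`, `w_below_min`, `w_above_max` (estimator);
#' `mode` (pipeline); `two_amine` (residue-table override, list of one-letter
#' codes). An explicit `seed` is required when `method` is `"mc"`.
#'
#' @param path YAML file.
#' @return list with elements `estimator` ([estimator_config()]), `mode`, and
#'   `residues` ([residue_table()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  pol <- w_policy(below_min = y$w_below_min %||% "clamp",
                  above_max = y$w_above_max %||% "clamp")
  est <- estimator_config(method = y$method %||% "quadrature",
                          resolution = y$grid_resolution %||% 400L,
                          n_samples = y$mc_samples %||% 1e6,
                          seed = y$seed,
                          alpha_max = y$alpha_max %||% 0.3,
                          beta_max = y$beta_max %||% 0.3,
                          policy = pol)
  tab <- if (is.null(y$two_amine)) residue_table()
         else residue_table(unlist(y$two_amine))
  list(estimator = est, mode = y$mode %||% "pointwise", residues = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
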