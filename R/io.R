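# Brood-count tables: TSV with columns
#   cross_id  vial_id  stage  n_female  n_male  n_eggs
# stage is "embryo" or "subadult"; n_eggs may be empty.

check_counts <- function(df, where = "table") {
  for (col in intersect(c("n_female", "n_male", "n_eggs"), names(df))) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v != round(v)))
    if (length(bad)) {
      stop(sprintf("%s: column '%s' has negative or non-integer counts in row(s) %s",
                   where, col, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(df)
}

validate_brood_table <- function(df, where = "brood table") {
  need <- c("cross_id", "vial_id", "stage", "n_female", "n_male")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(where, " is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$stage %in% c("embryo", "subadult"))
  if (length(bad)) {
    stop(sprintf("%s: invalid stage '%s' in row(s) %s (expected 'embryo' or 'subadult')",
                 where, df$stage[bad[1]], paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  check_counts(df, where)
  if (!"n_eggs" %in% names(df)) df$n_eggs <- NA_integer_
  over <- which(!is.na(df$n_eggs) & df$stage == "subadult" &
                df$n_female + df$n_male > df$n_eggs)
  if (length(over)) {
    stop(sprintf("%s: subadult counts exceed the egg count in row(s) %s",
                 where, paste(over, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and write brood-count tables
#'
#' Brood tables are UTF-8 TSV files with one row per vial and census stage:
#' columns `cross_id`, `vial_id`, `stage` (`"embryo"` or `"subadult"`),
#' `n_female`, `n_male`, and optionally `n_eggs`. Malformed rows are
#' reported with their row numbers; negative or non-integer counts and
#' subadult totals exceeding the egg count are rejected.
#'
#' @param path file path.
#' @return `read_brood_table()` returns a validated data.frame.
#' @examples
#' sr <- line_spec("SR", driver = TRUE)
#' cr <- cross_spec(line_genotype(sr, "male"), line_genotype(sr, "female"),
#'                  "SRxSR")
#' b <- simulate_cross(cr, mechanism_params(s_Y = 0.3), n_vials = 2, seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' write_brood_table(b, tf)
#' identical(read_brood_table(tf), b)
#' @export
read_brood_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_brood_table(df, where = path)
}

#' @rdname read_brood_table
#' @param broods a brood-count data.frame.
#' @export
write_brood_table <- function(broods, path) {
  validate_brood_table(broods)
  utils::write.table(broods, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# serialize mechanism params to a plain list (YAML/JSON friendly)
params_to_list <- function(p) {
  out <- unclass(p)
  out$suppressors <- lapply(p$suppressors, function(s)
    list(name = s$name, targets = s$targets, acts_in = s$acts_in))
  out
}

params_from_list <- function(x) {
  sup <- lapply(x$suppressors, function(s)
    suppressor(s$name, unlist(s$targets), s$acts_in))
  x$suppressors <- sup
  do.call(mechanism_params, x)
}

#' Read and write mechanism parameters as YAML
#'
#' The simulator writes its generating parameters alongside each synthetic
#' dataset so parameter-recovery analyses can compare estimates against the
#' truth.
#'
#' @param params a [mechanism_params()] object.
#' @param path file path.
#' @return `read_mechanism_params()` returns a [mechanism_params()] object.
#' @export
write_mechanism_params <- function(params, path) {
  validate_mechanism_params(params)
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' @rdname write_mechanism_params
#' @export
read_mechanism_params <- function(path) {
  params_from_list(yaml::read_yaml(path))
}
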