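#' Classify sire families and bound the map distance
#'
#' Applies the two-tier classification of the recombination assay: every
#' informative sire (one that produced offspring) gets a one-sided exact
#' binomial test of female bias in his primary family; sires whose primary
#' family is not significant are *rescued* if at least one of their grandson
#' families is significantly female-biased (a carrier mother transmits the
#' driver to each grandson with probability 1/2, so testing `k` grandsons
#' detects her with probability `1 - (1/2)^k`). Sires negative in both tiers
#' form the null (no-driver) class, whose proportion — divided by the
#' detectable fraction of recombinant gametes — estimates the recombination
#' distance between the two drivers.
#'
#' @param data a `linkage_assay_data` object from
#'   [simulate_recombination_assay()] or [read_linkage_table()].
#' @param alpha one-sided level of the per-family exact binomial test.
#' @param detect_fraction detectable fraction of recombinant gametes
#'   (default 1/2: only the no-driver class is recognizable).
#' @param min_grandson_family grandson families smaller than this are
#'   discarded before testing (size filter for adequate power).
#' @return an object of class `linkage_result`: `sires` (per-sire calls:
#'   `significant`, `followed_up`, `rescued`, `null_class`),
#'   `n_informative`, `n_null_class`, `rescued_sires`, and `bound` (the
#'   [recombination_upper_bound()] output).
#' @examples
#' ad <- simulate_recombination_assay(r = 0, penetrance = 0.9,
#'                                    n_sires = 60, seed = 1)
#' classify_families(ad)
#' @export
classify_families <- function(data, alpha = 0.05, detect_fraction = 0.5,
                              min_grandson_family = 0) {
  stopifnot(inherits(data, "linkage_assay_data"))
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must lie in (0, 0.5)",
                                       call. = FALSE)
  s <- data$sires
  n_tot <- s$n_female + s$n_male
  informative <- n_tot > 0
  pval <- family_bias_pvalue(s$n_female, n_tot)
  significant <- informative & pval < alpha

  gs <- data$grandsons
  gs <- gs[gs$n_female + gs$n_male >= min_grandson_family, , drop = FALSE]
  # the follow-up asks one question per sire (was the mother heterozygous?)
  # across k grandson families, so the per-family level is Bonferroni
  # adjusted to keep the sire-wise spurious-rescue rate at alpha
  gs_p <- family_bias_pvalue(gs$n_female, gs$n_female + gs$n_male)
  gs_k <- table(gs$sire_id)
  gs_sig <- gs$sire_id[gs_p < alpha / as.vector(gs_k[gs$sire_id])]
  followed_up <- s$sire_id %in% unique(data$grandsons$sire_id)
  rescued <- !significant & informative & s$sire_id %in% gs_sig
  null_class <- informative & !significant & !rescued

  n_informative <- sum(informative)
  n_null <- sum(null_class)
  bound <- recombination_upper_bound(n_informative, n_null, alpha,
                                     detect_fraction)
  calls <- data.frame(sire_id = s$sire_id, n = n_tot,
                      pf = ifelse(n_tot > 0, 100 * s$n_female / n_tot, NA),
                      p_value = pval, informative = informative,
                      significant = significant, followed_up = followed_up,
                      rescued = rescued, null_class = null_class)
  structure(list(sires = calls, n_informative = n_informative,
                 n_null_class = n_null,
                 rescued_sires = s$sire_id[rescued], bound = bound,
                 alpha = alpha),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Two-driver recombination assay\n")
  cat(sprintf("  informative sires:      %d\n", x$n_informative))
  cat(sprintf("  primary significant:    %d\n", sum(x$sires$significant)))
  cat(sprintf("  rescued by grandsons:   %d\n", length(x$rescued_sires)))
  cat(sprintf("  null (no-driver) class: %d\n", x$n_null_class))
  cat(sprintf("  map distance: point %.2f cM, %d%% upper bound %.2f cM%s\n",
              x$bound$point_cM, round(100 * (1 - x$alpha)),
              x$bound$upper_cM,
              if (x$bound$unlinked) " (unlinked)" else ""))
  invisible(x)
}

#' Read and write linkage-assay tables
#'
#' The linkage assay shares the brood-count TSV schema, extended with two
#' lineage columns: `sire_id` and `tier` (`"primary"` or `"grandson"`), plus
#' `grandson_id` for the follow-up tier. True carrier classes, if present
#' (simulated data), travel in `true_class` / `true_carrier` columns.
#'
#' @param path file path.
#' @return `read_linkage_table()` returns a `linkage_assay_data` object.
#' @export
read_linkage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sire_id", "tier", "n_female", "n_male")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("linkage table is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$tier %in% c("primary", "grandson"))
  if (length(bad)) stop("invalid tier in row(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  check_counts(df, path)
  pri <- df[df$tier == "primary", ]
  gs <- df[df$tier == "grandson", ]
  sires <- data.frame(sire_id = pri$sire_id, n_female = pri$n_female,
                      n_male = pri$n_male,
                      true_class = if ("true_class" %in% names(pri))
                        pri$true_class else NA_character_)
  if (!"grandson_id" %in% names(gs)) {
    gs$grandson_id <- make.unique(as.character(gs$sire_id))
  }
  tc <- if ("true_carrier" %in% names(gs)) gs$true_carrier
        else if ("true_class" %in% names(gs)) gs$true_class
        else rep(NA, nrow(gs))
  grandsons <- data.frame(sire_id = gs$sire_id, grandson_id = gs$grandson_id,
                          n_female = gs$n_female, n_male = gs$n_male,
                          true_carrier = as.logical(tc))
  structure(list(sires = sires, grandsons = grandsons, settings = list()),
            class = "linkage_assay_data")
}

#' @rdname read_linkage_table
#' @param data a `linkage_assay_data` object.
#' @export
write_linkage_table <- function(data, path) {
  stopifnot(inherits(data, "linkage_assay_data"))
  pri <- data.frame(sire_id = data$sires$sire_id, tier = "primary",
                    grandson_id = NA_character_,
                    n_female = data$sires$n_female,
                    n_male = data$sires$n_male,
                    true_class = data$sires$true_class)
  gs <- data$grandsons
  out <- pri
  if (nrow(gs)) {
    gs_rows <- data.frame(sire_id = gs$sire_id, tier = "grandson",
                          grandson_id = gs$grandson_id,
                          n_female = gs$n_female, n_male = gs$n_male,
                          true_class = as.character(gs$true_carrier))
    out <- rbind(pri, gs_rows)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
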