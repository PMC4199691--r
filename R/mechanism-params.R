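#' Quantitative switches for each sex-ratio-distorting etiology
#'
#' A `mechanism_params` object collects, in one place, the strength of every
#' mechanism that can bias a brood sex ratio away from 50% females. All
#' survival parameters are *relative* survivals in `[0, 1]` (1 = neutral, the
#' mechanism is off); probabilities are in `[0, 1]` (0 = off). With every
#' field at its neutral value any cross is expected to yield exactly 50%
#' females.
#'
#' Which mechanisms actually act in a given cross is decided by the parental
#' [genotype()]s, not by the parameters themselves: the paternal-effect
#' chain (`s_Y`, `s_son_embryo`, `s_son_post`) fires only when the sire
#' carries a driver X; son-killing (`sk_son_survival`), cytoplasmic
#' feminization and asexuality fire only when the dam's cytoplasm is
#' infected; constitutive viability is keyed to the offspring's autosomal
#' genotype.
#'
#' @param s_Y relative survival/functionality of Y-bearing sperm produced by
#'   a driver-carrying sire (segregation distortion; 1 = none). Acts before
#'   syngamy, so it reweights zygote sex without killing eggs.
#' @param s_son_embryo paternal-effect relative survival of sons up to the
#'   stage at which embryos are sexed.
#' @param s_son_post paternal-effect relative survival of sons from the
#'   embryo census to the subadult census. This is the zygotic-drive
#'   component proper.
#' @param v_male constitutive (offspring-genotype-determined) male relative
#'   viability. Applies to males whose autosomal genotype at the killer
#'   locus matches `v_male_dominance`.
#' @param v_male_dominance `"recessive"` (male must be homozygous for the
#'   focal line's autosomes at the locus) or `"dominant"` (one dose
#'   suffices).
#' @param v_male_origin line tag of the autosomes carrying the killer locus
#'   (default `"SR"`); only doses derived from this line activate `v_male`.
#' @param sk_son_survival endosymbiont-induced relative survival of infected
#'   sons of infected dams (son-killing; 1 = none).
#' @param sk_transmission maternal transmission probability of the
#'   endosymbiont.
#' @param p_fem_cyto,p_fem_x,p_fem_y probabilities that an XY zygote develops
#'   as a phenotypic female under cytoplasmic, X-linked, or Y-linked
#'   feminization. The cytoplasmic route requires an infected embryo; the X
#'   and Y routes require the relevant chromosome to come from the focal
#'   (driver) line.
#' @param asex_fraction fraction of an infected dam's offspring produced
#'   asexually (all daughters).
#' @param penetrance probability that a driver-carrying sire expresses the
#'   drive phenotype at all. Resolved once per sire: a non-expressing sire
#'   is completely inert for `s_Y`, `s_son_embryo` and `s_son_post`.
#' @param suppressors list of [suppressor()] definitions describing which
#'   parameters are restored to their neutral value when the suppressor
#'   allele is present in the relevant individual.
#'
#' @return an object of class `mechanism_params`.
#' @seealso [suppressor()], [expected_embryo_pf()], [simulate_cross()]
#' @examples
#' # segregation distortion plus paternal-effect son killing
#' mechanism_params(s_Y = 0.307, s_son_post = 0.625)
#' @export
mechanism_params <- function(s_Y = 1,
                             s_son_embryo = 1,
                             s_son_post = 1,
                             v_male = 1,
                             v_male_dominance = c("recessive", "dominant"),
                             v_male_origin = "SR",
                             sk_son_survival = 1,
                             sk_transmission = 1,
                             p_fem_cyto = 0,
                             p_fem_x = 0,
                             p_fem_y = 0,
                             asex_fraction = 0,
                             penetrance = 1,
                             suppressors = list()) {
  v_male_dominance <- match.arg(v_male_dominance)
  p <- list(
    s_Y = s_Y, s_son_embryo = s_son_embryo, s_son_post = s_son_post,
    v_male = v_male, v_male_dominance = v_male_dominance,
    v_male_origin = v_male_origin,
    sk_son_survival = sk_son_survival, sk_transmission = sk_transmission,
    p_fem_cyto = p_fem_cyto, p_fem_x = p_fem_x, p_fem_y = p_fem_y,
    asex_fraction = asex_fraction, penetrance = penetrance,
    suppressors = suppressors
  )
  class(p) <- "mechanism_params"
  validate_mechanism_params(p)
}

validate_mechanism_params <- function(p) {
  num_fields <- c("s_Y", "s_son_embryo", "s_son_post", "v_male",
                  "sk_son_survival", "sk_transmission",
                  "p_fem_cyto", "p_fem_x", "p_fem_y",
                  "asex_fraction", "penetrance")
  for (f in num_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("mechanism parameter '", f, "' must be a single value in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.list(p$suppressors) ||
      !all(vapply(p$suppressors, inherits, logical(1), "sazd_suppressor"))) {
    stop("'suppressors' must be a list of suppressor() objects", call. = FALSE)
  }
  p
}

#' Declare a suppressor of one or more drive mechanisms
#'
#' A suppressor is an allele (autosomal dominant, or a property of a whole Y
#' chromosome) that restores one or more mechanism parameters to their
#' neutral value when present in the relevant individual. Two scopes are
#' supported: `acts_in = "sire"` (the allele silences the mechanism in the
#' sire's germline, e.g. autosomal dominant suppressors of segregation
#' distortion, or a heterospecific Y that silences both the gametic and the
#' zygotic phenotype) and `acts_in = "offspring"` (the allele rescues the
#' offspring that carries it, e.g. a Y that protects sons from endosymbiont
#' son-killing).
#'
#' @param name suppressor identifier (matched against genotype carrier
#'   flags).
#' @param targets character vector of mechanism parameter names the
#'   suppressor restores to neutral; any of `"s_Y"`, `"s_son_embryo"`,
#'   `"s_son_post"`, `"v_male"`, `"sk_son_survival"`.
#' @param acts_in `"sire"` or `"offspring"`.
#' @return an object of class `sazd_suppressor`.
#' @examples
#' # autosomal dominant suppressor of sperm killing, acting in the sire
#' suppressor("Nmy-like", targets = "s_Y", acts_in = "sire")
#' # a Y that silences both drive components in the sire's germline
#' suppressor("sec", targets = c("s_Y", "s_son_post"), acts_in = "sire")
#' @export
suppressor <- function(name, targets,
                       acts_in = c("sire", "offspring")) {
  acts_in <- match.arg(acts_in)
  ok <- c("s_Y", "s_son_embryo", "s_son_post", "v_male", "sk_son_survival")
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("suppressor 'name' must be a non-empty string", call. = FALSE)
  }
  if (!all(targets %in% ok)) {
    stop("suppressor targets must be among: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, targets = unique(targets), acts_in = acts_in),
            class = "sazd_suppressor")
}

#' @export
print.mechanism_params <- function(x, ...) {
  cat("Mechanism parameters\n")
  lab <- c(s_Y = "Y-sperm survival (SD)",
           s_son_embryo = "paternal son survival, pre-census",
           s_son_post = "paternal son survival, post-census (SA-ZD)",
           v_male = "constitutive male viability",
           sk_son_survival = "endosymbiont son survival (SK)",
           sk_transmission = "endosymbiont transmission",
           p_fem_cyto = "P(feminize | cyto)",
           p_fem_x = "P(feminize | X)",
           p_fem_y = "P(feminize | Y)",
           asex_fraction = "asexual daughter fraction",
           penetrance = "sire penetrance")
  for (f in names(lab)) {
    cat(sprintf("  %-42s %.4g\n", lab[[f]], x[[f]]))
  }
  cat("  dominance of viability locus:", x$v_male_dominance, "\n")
  if (length(x$suppressors)) {
    for (s in x$suppressors) {
      cat(sprintf("  suppressor '%s' (%s): %s\n",
                  s$name, s$acts_in, paste(s$targets, collapse = ", ")))
    }
  }
  invisible(x)
}

# gather suppressor definitions from one or more params objects, de-duplicated
# by name (later definitions win)
collect_suppressors <- function(...) {
  defs <- list()
  for (p in list(...)) {
    if (is.null(p)) next
    for (s in p$suppressors) defs[[s$name]] <- s
  }
  defs
}
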