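#' Construct an individual genotype
#'
#' Genotypes carry the information the drive model needs to decide which
#' mechanisms act in a cross: the X allele(s) with their line of origin and
#' driver status, the Y origin, the autosomal line composition (as per-allele
#' dose fractions), the cytoplasm origin with its infection flag, and any
#' suppressor alleles carried on the Y or the autosomes.
#'
#' Phenotypic sex follows the standard karyotype (XX female, XY male) except
#' for compound-X females, which carry a fused double-X plus a Y and transmit
#' the double-X to daughters and their Y to sons. Feminization mechanisms
#' override phenotypic sex downstream, in the model, not here.
#'
#' @param x_origin character vector of X-allele line tags (length 1 for
#'   males and compound-X females, length 2 for standard females; the
#'   compound-X counts as one fused allele).
#' @param x_driver logical vector parallel to `x_origin`: does the allele
#'   carry the driver?
#' @param y Y-chromosome line tag, or `NA` for standard females.
#' @param compound_x logical; fused double-X female carrying a Y.
#' @param aut_dose named numeric vector: for each line tag, the probability
#'   that a random autosomal allele of this individual derives from that
#'   line. Values must be in `[0, 1]` and sum to 1.
#' @param cytoplasm cytoplasm line tag (maternally inherited).
#' @param infected logical; endosymbiont infection of the cytoplasm.
#' @param y_suppressors character vector of suppressor names carried on the
#'   Y chromosome.
#' @param aut_suppressors named numeric vector of autosomal suppressor
#'   transmission probabilities (0.5 heterozygous, 1 homozygous); the
#'   individual is a carrier of every named allele.
#'
#' @return an object of class `sazd_genotype` with a derived `$sex`.
#' @examples
#' sire <- genotype("SR", x_driver = TRUE, y = "SR", aut_dose = c(SR = 1))
#' dam  <- genotype(c("SR", "SR"), x_driver = c(TRUE, TRUE),
#'                  aut_dose = c(SR = 1))
#' @export
genotype <- function(x_origin, x_driver = rep(FALSE, length(x_origin)),
                     y = NA_character_, compound_x = FALSE,
                     aut_dose = c(SR = 1), cytoplasm = x_origin[[1]],
                     infected = FALSE,
                     y_suppressors = character(),
                     aut_suppressors = numeric(0)) {
  if (length(x_origin) < 1L) stop("a genotype must carry at least one X",
                                  call. = FALSE)
  stopifnot(is.character(x_origin), length(x_origin) %in% 1:2,
            is.logical(x_driver), length(x_driver) == length(x_origin),
            is.logical(compound_x), length(compound_x) == 1L)
  if (!is.numeric(aut_dose) || is.null(names(aut_dose)) ||
      any(aut_dose < 0 | aut_dose > 1) || abs(sum(aut_dose) - 1) > 1e-8) {
    stop("'aut_dose' must be a named numeric vector in [0,1] summing to 1",
         call. = FALSE)
  }
  has_y <- !is.na(y)
  sex <- if (compound_x) {
    if (!has_y || length(x_origin) != 1L) {
      stop("a compound-X female carries one fused double-X plus a Y",
           call. = FALSE)
    }
    "female"
  } else if (length(x_origin) == 2L && !has_y) {
    "female"
  } else if (length(x_origin) == 1L && has_y) {
    "male"
  } else {
    stop("karyotype must be XX (female), XY (male) or compound-X + Y",
         call. = FALSE)
  }
  structure(list(
    sex = sex, x_origin = x_origin, x_driver = x_driver,
    y = y, compound_x = compound_x, aut_dose = aut_dose,
    cytoplasm = cytoplasm, infected = isTRUE(infected),
    y_suppressors = y_suppressors, aut_suppressors = aut_suppressors
  ), class = "sazd_genotype")
}

#' @export
print.sazd_genotype <- function(x, ...) {
  xs <- paste0("X_", x$x_origin, ifelse(x$x_driver, "*", ""),
               collapse = if (x$compound_x) "^" else " ")
  ys <- if (is.na(x$y)) "" else paste0(" Y_", x$y)
  cat(sprintf("<genotype %s: %s%s | aut: %s | cyto: %s%s>\n",
              x$sex, xs, ys,
              paste(sprintf("%s=%.3g", names(x$aut_dose), x$aut_dose),
                    collapse = ","),
              x$cytoplasm, if (x$infected) " (infected)" else ""))
  invisible(x)
}

#' Line specification and line individuals
#'
#' A line spec describes an inbred stock: its tag, whether its X carries the
#' driver, whether its cytoplasm is infected, and any suppressors it is
#' fixed for. [line_genotype()] materializes a male or female individual
#' drawn from the line (homozygous/isogenic).
#'
#' @param name line tag, e.g. `"SR"`, `"EVEN"`, `"Paris"`.
#' @param driver logical; the line's X carries the driver.
#' @param infected logical; the line's cytoplasm carries the endosymbiont.
#' @param y_suppressors suppressor names fixed on the line's Y.
#' @param aut_suppressors character vector of autosomal suppressor names the
#'   line is fixed for (homozygous; transmission probability 1).
#' @return `line_spec()` returns a `sazd_line` object; `line_genotype()` a
#'   [genotype()].
#' @examples
#' sr <- line_spec("SR", driver = TRUE)
#' line_genotype(sr, "male")
#' @export
line_spec <- function(name, driver = FALSE, infected = FALSE,
                      y_suppressors = character(),
                      aut_suppressors = character()) {
  structure(list(name = name, driver = driver, infected = infected,
                 y_suppressors = y_suppressors,
                 aut_suppressors = aut_suppressors),
            class = "sazd_line")
}

#' @rdname line_spec
#' @param line a `sazd_line` object.
#' @param sex `"male"` or `"female"`.
#' @export
line_genotype <- function(line, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(inherits(line, "sazd_line"))
  aut_sup <- stats::setNames(rep(1, length(line$aut_suppressors)),
                             line$aut_suppressors)
  dose <- stats::setNames(1, line$name)
  if (sex == "male") {
    genotype(line$name, x_driver = line$driver, y = line$name,
             aut_dose = dose, cytoplasm = line$name,
             infected = line$infected,
             y_suppressors = line$y_suppressors, aut_suppressors = aut_sup)
  } else {
    genotype(c(line$name, line$name),
             x_driver = c(line$driver, line$driver),
             aut_dose = dose, cytoplasm = line$name,
             infected = line$infected, aut_suppressors = aut_sup)
  }
}

#' Specify a cross between two genotypes
#'
#' @param sire a phenotypically male [genotype()].
#' @param dam a phenotypically female [genotype()].
#' @param label generation/step identifier (e.g. `"P0"`, `"step2a"`).
#' @return an object of class `sazd_cross`.
#' @examples
#' sr <- line_spec("SR", driver = TRUE)
#' cross_spec(line_genotype(sr, "male"), line_genotype(sr, "female"), "SRxSR")
#' @export
cross_spec <- function(sire, dam, label = "cross") {
  stopifnot(inherits(sire, "sazd_genotype"), inherits(dam, "sazd_genotype"))
  if (sire$sex != "male") stop("'sire' must be phenotypically male",
                               call. = FALSE)
  if (dam$sex != "female") stop("'dam' must be phenotypically female",
                                call. = FALSE)
  if (length(sire$x_origin) < 1L || all(is.na(sire$x_origin))) {
    stop("malformed genotype: sire carries no X", call. = FALSE)
  }
  structure(list(sire = sire, dam = dam, label = label),
            class = "sazd_cross")
}

#' @export
print.sazd_cross <- function(x, ...) {
  cat("<cross", x$label, ">\n  sire: ")
  print(x$sire)
  cat("  dam:  ")
  print(x$dam)
  invisible(x)
}

#' Derive an offspring genotype by Mendelian transmission
#'
#' Sons receive one maternal X (chosen at random for heterozygous dams) and
#' the paternal Y; daughters receive one maternal X and the paternal X.
#' Compound-X dams transmit their fused double-X to daughters (who also get
#' the sire's Y) and their Y to sons (who get the sire's X). Autosomal dose
#' fractions average over the parents; autosomal suppressor copies are drawn
#' per parent with the parental transmission probability. Cytoplasm follows
#' the dam, with infection transmitted with probability `sk_transmission`.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param sire,dam parental [genotype()]s.
#' @param sex offspring sex, `"male"` or `"female"`.
#' @param sk_transmission maternal endosymbiont transmission probability.
#' @return a [genotype()].
#' @export
offspring_genotype <- function(sire, dam, sex = c("male", "female"),
                               sk_transmission = 1) {
  sex <- match.arg(sex)
  pick_dam_x <- function() {
    i <- if (length(dam$x_origin) == 2L) sample.int(2L, 1L) else 1L
    list(origin = dam$x_origin[[i]], driver = dam$x_driver[[i]])
  }
  nm <- union(names(sire$aut_dose), names(dam$aut_dose))
  dose <- (ifelse(nm %in% names(sire$aut_dose), sire$aut_dose[nm], 0) +
           ifelse(nm %in% names(dam$aut_dose), dam$aut_dose[nm], 0)) / 2
  names(dose) <- nm
  sup_names <- union(names(sire$aut_suppressors), names(dam$aut_suppressors))
  copies <- vapply(sup_names, function(s) {
    ts <- if (s %in% names(sire$aut_suppressors)) sire$aut_suppressors[[s]] else 0
    td <- if (s %in% names(dam$aut_suppressors)) dam$aut_suppressors[[s]] else 0
    stats::rbinom(1L, 1L, ts) + stats::rbinom(1L, 1L, td)
  }, integer(1))
  aut_sup <- stats::setNames(copies[copies > 0] / 2, sup_names[copies > 0])
  infected <- dam$infected && stats::runif(1) < sk_transmission

  if (sex == "male") {
    if (dam$compound_x) {
      x <- list(origin = sire$x_origin[[1]], driver = sire$x_driver[[1]])
      y <- dam$y; ysup <- character()  # dam's Y carries no tracked suppressors
    } else {
      x <- pick_dam_x()
      y <- sire$y; ysup <- sire$y_suppressors
    }
    genotype(x$origin, x_driver = x$driver, y = y, aut_dose = dose,
             cytoplasm = dam$cytoplasm, infected = infected,
             y_suppressors = ysup, aut_suppressors = aut_sup)
  } else {
    if (dam$compound_x) {
      genotype(dam$x_origin, x_driver = dam$x_driver, y = sire$y,
               compound_x = TRUE, aut_dose = dose,
               cytoplasm = dam$cytoplasm, infected = infected,
               y_suppressors = sire$y_suppressors, aut_suppressors = aut_sup)
    } else {
      mx <- pick_dam_x()
      genotype(c(mx$origin, sire$x_origin[[1]]),
               x_driver = c(mx$driver, sire$x_driver[[1]]),
               aut_dose = dose, cytoplasm = dam$cytoplasm,
               infected = infected, aut_suppressors = aut_sup)
    }
  }
}
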