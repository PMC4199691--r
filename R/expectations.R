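# Closed-form sex-ratio expectations.
#
# The engine reduces a cross to a small set of "mechanics": per-egg class
# probabilities at syngamy, per-son feminization and infection
# probabilities, and male survival factors at the embryo and post-embryo
# stages, with suppressor overrides resolved per carrier. Both the analytic
# expectations and the forward simulator consume the same mechanics, so the
# simulator converges to the closed forms by construction of the model, and
# the tests verify that it does.

# params_for: function(line_tag) -> mechanism_params. The single-params API
# uses the same parameter set for every line of origin; activation is gated
# by genotype flags, so components from a neutral line stay inert.
params_lookup <- function(params, params_even = NULL, even_tag = "EVEN") {
  force(params); force(params_even); force(even_tag)
  function(origin) {
    if (!is.null(params_even) && identical(origin, even_tag)) params_even
    else params
  }
}

restore1 <- function(value, restored) if (restored) 1 else value

cross_mechanics <- function(cross, params_for) {
  sire <- cross$sire
  dam <- cross$dam
  carried_by_sire <- c(sire$y_suppressors, names(sire$aut_suppressors))

  # paternal-effect chain, keyed to the sire's driver X
  driver <- any(sire$x_driver)
  drv_origin <- if (driver) sire$x_origin[which(sire$x_driver)[1]] else NA
  pat <- list(s_Y = 1, s_son_embryo = 1, s_son_post = 1, penetrance = 1)
  defs <- collect_suppressors(params_for(sire$x_origin[[1]]),
                              params_for(dam$x_origin[[1]]),
                              params_for(dam$cytoplasm),
                              if (driver) params_for(drv_origin))
  if (driver) {
    pp <- params_for(drv_origin)
    pat$s_Y <- pp$s_Y
    pat$s_son_embryo <- pp$s_son_embryo
    pat$s_son_post <- pp$s_son_post
    pat$penetrance <- pp$penetrance
    for (s in defs) {
      if (s$acts_in == "sire" && s$name %in% carried_by_sire) {
        for (tg in intersect(s$targets,
                             c("s_Y", "s_son_embryo", "s_son_post"))) {
          pat[[tg]] <- 1
        }
      }
    }
  }

  # maternal cytoplasm: son-killing, cytoplasmic feminization, asexuality
  pd <- params_for(dam$cytoplasm)
  p_asex <- if (dam$infected) pd$asex_fraction else 0
  p_inf_son <- if (dam$infected) pd$sk_transmission else 0
  sk_s <- pd$sk_son_survival
  p_fem_cyto <- p_inf_son * pd$p_fem_cyto

  # X- and Y-linked feminization, keyed to the chromosome the son receives
  if (dam$compound_x) {
    son_x_origin <- sire$x_origin[[1]]
    p_fem_x <- params_for(son_x_origin)$p_fem_x
    son_y_origin <- dam$y
    son_y_sup <- dam$y_suppressors
  } else {
    p_fem_x <- mean(vapply(dam$x_origin,
                           function(o) params_for(o)$p_fem_x, numeric(1)))
    son_y_origin <- sire$y
    son_y_sup <- sire$y_suppressors
  }
  p_fem_y <- if (is.na(son_y_origin)) 0 else params_for(son_y_origin)$p_fem_y
  fem_p <- 1 - (1 - p_fem_cyto) * (1 - p_fem_x) * (1 - p_fem_y)

  # constitutive male viability, per line of autosomal origin
  lines <- union(names(sire$aut_dose), names(dam$aut_dose))
  v_terms <- list()
  for (L in lines) {
    pl <- params_for(L)
    if (pl$v_male >= 1 || !identical(L, pl$v_male_origin)) next
    ds <- if (L %in% names(sire$aut_dose)) sire$aut_dose[[L]] else 0
    dd <- if (L %in% names(dam$aut_dose)) dam$aut_dose[[L]] else 0
    p_act <- if (pl$v_male_dominance == "recessive") ds * dd
             else 1 - (1 - ds) * (1 - dd)
    if (p_act > 0) v_terms[[L]] <- list(p_act = p_act, v = pl$v_male)
  }

  # offspring-acting suppressors: carriage probability of a son
  off_supp <- list()
  for (s in defs) {
    if (s$acts_in != "offspring") next
    q_y <- as.numeric(s$name %in% son_y_sup)
    ts <- if (s$name %in% names(sire$aut_suppressors))
      sire$aut_suppressors[[s$name]] else 0
    td <- if (s$name %in% names(dam$aut_suppressors))
      dam$aut_suppressors[[s$name]] else 0
    q <- 1 - (1 - q_y) * (1 - ts) * (1 - td)
    if (q > 0) off_supp[[s$name]] <- list(q = q, targets = s$targets)
  }

  list(driver = driver, pat = pat, p_asex = p_asex,
       p_inf_son = p_inf_son, sk_s = sk_s, fem_p = fem_p,
       v_terms = v_terms, off_supp = off_supp)
}

# male survival factors given expression status and a carried-suppressor set
male_survival <- function(mech, expressed, carried = character()) {
  has <- function(tg) {
    any(vapply(mech$off_supp[carried],
               function(s) tg %in% s$targets, logical(1)))
  }
  s_emb <- if (expressed && !has("s_son_embryo")) mech$pat$s_son_embryo else 1
  s_post <- if (expressed && !has("s_son_post")) mech$pat$s_son_post else 1
  v <- if (has("v_male") || !length(mech$v_terms)) 1 else
    prod(vapply(mech$v_terms,
                function(t) 1 - t$p_act * (1 - t$v), numeric(1)))
  sk <- if (has("sk_son_survival")) 1 else
    1 - mech$p_inf_son * (1 - mech$sk_s)
  list(embryo = s_emb, post = s_post * v * sk)
}

# enumerate carried-suppressor subsets with their probabilities
supp_subsets <- function(off_supp) {
  nm <- names(off_supp)
  if (!length(nm)) return(list(list(carried = character(), p = 1)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nm)))
  lapply(seq_len(nrow(grid)), function(i) {
    on <- as.logical(grid[i, ])
    q <- vapply(off_supp, function(s) s$q, numeric(1))
    list(carried = nm[on], p = prod(ifelse(on, q, 1 - q)))
  })
}

# expected class weights per egg for one expression status
class_weights <- function(mech, expressed) {
  s_Y <- if (expressed) mech$pat$s_Y else 1
  p_m <- (1 - mech$p_asex) * s_Y / (1 + s_Y)
  p_f <- 1 - p_m
  m_fem <- p_m * mech$fem_p
  m_true <- p_m * (1 - mech$fem_p)
  emb <- 0; sub <- 0
  for (ss in supp_subsets(mech$off_supp)) {
    s <- male_survival(mech, expressed, ss$carried)
    emb <- emb + ss$p * s$embryo
    sub <- sub + ss$p * s$embryo * s$post
  }
  list(f = p_f, m_fem = m_fem,
       m_embryo = m_true * emb, m_subadult = m_true * sub)
}

expected_pf <- function(cross, params_for, stage, sexing) {
  mech <- cross_mechanics(cross, params_for)
  pen <- mech$pat$penetrance  # 1 unless the sire carries a driver X
  f <- m <- 0
  for (e in c(TRUE, FALSE)) {
    w <- if (e) pen else 1 - pen
    if (w <= 0) next
    cw <- class_weights(mech, expressed = e && mech$driver)
    if (stage == "embryo") {
      if (sexing == "phenotype") {
        f <- f + w * (cw$f + cw$m_fem)
        m <- m + w * cw$m_embryo
      } else {
        f <- f + w * cw$f
        m <- m + w * (cw$m_fem + cw$m_embryo)
      }
    } else {
      f <- f + w * (cw$f + cw$m_fem)
      m <- m + w * cw$m_subadult
    }
  }
  100 * f / (f + m)
}

check_pf_args <- function(params, cross) {
  if (!inherits(params, "mechanism_params")) {
    stop("'params' must be a mechanism_params object", call. = FALSE)
  }
  validate_mechanism_params(params)
  if (!inherits(cross, "sazd_cross")) {
    stop("'cross' must be a cross_spec object", call. = FALSE)
  }
  if (length(cross$sire$x_origin) < 1L || anyNA(cross$sire$x_origin)) {
    stop("malformed genotype: sire carries no X", call. = FALSE)
  }
}

#' Expected percent-female at the embryo and subadult census
#'
#' Exact expectations of the pooled percent-female among censused offspring
#' of a cross, under the mechanism model. At syngamy the female share is 1/2
#' (plus any asexual daughters) and the male share is weighted by the
#' relative survival of Y-bearing sperm; paternal-effect son mortality then
#' thins sons up to the embryo census (`s_son_embryo`) and from there to the
#' subadult census (`s_son_post`), multiplied by constitutive viability and
#' endosymbiont son-killing terms where the offspring genotype and maternal
#' cytoplasm activate them. Suppressors are applied before survivals;
#' feminized XY individuals develop — and survive — as females, and are
#' counted as female whenever sexing is phenotype-based.
#'
#' Because segregation distortion acts on sperm while zygotic drive acts on
#' the surviving male zygotes, the two compose sequentially: the subadult
#' expectation with `s_Y = a, s_son_post = b` equals the embryo expectation
#' with a single `s_Y = a * b` when no other embryo-stage male mortality is
#' active.
#'
#' @param params a [mechanism_params()] object.
#' @param cross a [cross_spec()].
#' @param sexing how embryos are sexed: `"phenotype"` (e.g. staining a
#'   sex-specific protein: feminized XY embryos count as female) or
#'   `"karyotype"` (they count as male).
#' @return percent-female in `[0, 100]`.
#' @examples
#' sr <- line_spec("SR", driver = TRUE)
#' srxsr <- cross_spec(line_genotype(sr, "male"),
#'                     line_genotype(sr, "female"), "SRxSR")
#' expected_embryo_pf(mechanism_params(s_Y = 0.307), srxsr)     # ~76.5
#' expected_subadult_pf(mechanism_params(s_Y = 0.307,
#'                                       s_son_post = 0.625), srxsr) # ~83.9
#' @export
expected_embryo_pf <- function(params, cross,
                               sexing = c("phenotype", "karyotype")) {
  sexing <- match.arg(sexing)
  check_pf_args(params, cross)
  expected_pf(cross, params_lookup(params), "embryo", sexing)
}

#' @rdname expected_embryo_pf
#' @export
expected_subadult_pf <- function(params, cross) {
  check_pf_args(params, cross)
  expected_pf(cross, params_lookup(params), "subadult", "phenotype")
}
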