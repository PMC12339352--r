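# Three-factor ANOVA and REML variance components feeding the
# multi-environment broad-sense heritability.

#' Simulate a balanced additive multi-environment trial for one trait
#'
#' Direct generative counterpart of the random-effects model fitted by
#' [estimate_variance_components()]:
#' `y_ijl = mu + g_i + year_j + treat_l + gy_ij + gl_il + e_ijl`, every effect
#' an independent normal draw at the stated variance. This is the harness for
#' variance-component and heritability parameter recovery; the multiplicative
#' stress generator ([simulate_phenotypes()]) is the trial fixture for the
#' tolerance-score and GWAS chains but does not carry additive VAL/VAY truths.
#'
#' @param n_accessions Number of genotypes.
#' @param VA,VAY,VAL,Ve Genotype, genotype-by-year, genotype-by-treatment and
#'   residual variances.
#' @param var_year,var_treatment Variances of the year and treatment main
#'   effects (0 gives an exact null for those F tests).
#' @param n_years Number of years (default 2; treatments fixed at CK/AK).
#' @param mu Grand mean.
#' @param trait Trait label for the output table.
#' @param seed Seed.
#' @return Long phenotype data.frame (accession, year, treatment, trait,
#'   value) with attribute `truth` (the variance components and L, Y).
#' @export
simulate_balanced_trial <- function(n_accessions, VA = 1, VAY = 0.5, VAL = 0.25,
                                    Ve = 1, var_year = 0, var_treatment = 0,
                                    n_years = 2, mu = 10, trait = "T1",
                                    seed = 1) {
  set.seed(as.integer(seed))
  n <- n_accessions
  acc <- paste0("S", seq_len(n))
  years <- 2016L + seq_len(n_years) - 1L
  treats <- c("CK", "AK")
  g <- stats::rnorm(n, 0, sqrt(VA))
  yj <- stats::rnorm(n_years, 0, sqrt(var_year))
  ll <- stats::rnorm(2, 0, sqrt(var_treatment))
  gy <- matrix(stats::rnorm(n * n_years, 0, sqrt(VAY)), n, n_years)
  gl <- matrix(stats::rnorm(n * 2, 0, sqrt(VAL)), n, 2)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n_years), l = 1:2)
  value <- mu + g[grid$i] + yj[grid$j] + ll[grid$l] +
    gy[cbind(grid$i, grid$j)] + gl[cbind(grid$i, grid$l)] +
    stats::rnorm(nrow(grid), 0, sqrt(Ve))
  out <- data.frame(accession = acc[grid$i], year = years[grid$j],
                    treatment = treats[grid$l], trait = trait, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(VA = VA, VAY = VAY, VAL = VAL, Ve = Ve,
                             L = 2L, Y = as.integer(n_years))
  out
}

#' Three-factor analysis of variance for one trait
#'
#' Least-squares fit with genotype (G), year (Y) and treatment (L) main
#' effects plus the G x Y and G x L interactions, sum-to-zero contrasts and
#' Type III sums of squares, each term tested against the residual mean
#' square. Matches the classical multi-environment trial ANOVA on possibly
#' unbalanced data.
#'
#' @param table Long phenotype data.frame.
#' @param trait Trait code.
#' @return One-row data.frame: F and p for G, Y, L, G:Y, G:L, their df, and
#'   the residual df and mean square.
#' @export
three_way_anova <- function(table, trait) {
  d <- table[table$trait == trait & !is.na(table$value), , drop = FALSE]
  d$G <- factor(d$accession); d$Y <- factor(d$year); d$L <- factor(d$treatment)
  if (nlevels(d$G) < 2 || nlevels(d$Y) < 2 || nlevels(d$L) < 2)
    stop("need >= 2 levels of genotype, year and treatment")
  old <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(old))
  fit <- stats::lm(value ~ G + Y + L + G:Y + G:L, data = d)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; aliased terms: ",
         paste(utils::head(unique(sub("[0-9]+$", "", aliased)), 5), collapse = ", "))
  }
  a <- car::Anova(fit, type = 3)
  term <- rownames(a)
  pick <- function(tm, col) a[match(tm, term), col]
  res_df <- a["Residuals", "Df"]
  data.frame(trait = trait,
             F_G = pick("G", "F value"), p_G = pick("G", "Pr(>F)"),
             F_Y = pick("Y", "F value"), p_Y = pick("Y", "Pr(>F)"),
             F_L = pick("L", "F value"), p_L = pick("L", "Pr(>F)"),
             F_GY = pick("G:Y", "F value"), p_GY = pick("G:Y", "Pr(>F)"),
             F_GL = pick("G:L", "F value"), p_GL = pick("G:L", "Pr(>F)"),
             df_G = pick("G", "Df"), df_Y = pick("Y", "Df"),
             df_L = pick("L", "Df"), df_GY = pick("G:Y", "Df"),
             df_GL = pick("G:L", "Df"), df_res = res_df,
             ms_res = a["Residuals", "Sum Sq"] / res_df,
             stringsAsFactors = FALSE)
}

#' REML variance components for one trait
#'
#' Mixed model with fixed intercept, year and treatment, and random genotype,
#' genotype-by-year and genotype-by-treatment effects:
#' `value ~ year + treatment + (1|G) + (1|G:Y) + (1|G:L)`, fitted by REML with
#' lme4. Estimates at the zero boundary are kept at 0 and flagged.
#'
#' @param table Long phenotype data.frame.
#' @param trait Trait code.
#' @return A `variance_components` list: VA (genotype), VAY (genotype x year),
#'   VAL (genotype x treatment), Ve (residual), L, Y, boundary flags, and the
#'   broad-sense heritability R (see [heritability()]).
#' @export
estimate_variance_components <- function(table, trait) {
  d <- table[table$trait == trait & !is.na(table$value), , drop = FALSE]
  d$G <- factor(d$accession); d$Y <- factor(d$year); d$L <- factor(d$treatment)
  if (nlevels(d$Y) < 2 || nlevels(d$L) < 2 || nlevels(d$G) < 2)
    stop("need >= 2 levels of each factor")
  fit <- tryCatch(
    lme4::lmer(value ~ Y + L + (1 | G) + (1 | G:Y) + (1 | G:L), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) stop("REML did not converge for ", trait, ": ",
                             conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  out <- list(trait = trait,
              VA = get("G"), VAY = get("G:Y"), VAL = get("G:L"),
              Ve = get("Residual"),
              L = nlevels(d$L), Y = nlevels(d$Y))
  out$boundary <- c(VA = out$VA < 1e-10, VAY = out$VAY < 1e-10,
                    VAL = out$VAL < 1e-10)
  out$R <- heritability(out)
  class(out) <- "variance_components"
  out
}

#' Multi-environment broad-sense heritability
#'
#' `R = VA / (VA + VAL/L + VAY/Y + Ve/(L*Y))`: the genotypic variance over the
#' variance of a genotype mean across L treatments and Y years. Increases in
#' VA, L and Y; lies in \[0, 1\].
#'
#' @param vc List with components VA, VAL, VAY, Ve, L, Y (e.g. from
#'   [estimate_variance_components()]).
#' @return R in \[0, 1\]; NA with a warning when every component is zero.
#' @export
heritability <- function(vc) {
  with(vc, {
    if (any(c(VA, VAL, VAY, Ve) < 0)) stop("variance components must be >= 0")
    if (L < 1 || Y < 1) stop("L and Y must be >= 1")
    denom <- VA + VAL / L + VAY / Y + Ve / (L * Y)
    if (denom == 0) {
      warning("all variance components zero: heritability undefined")
      return(NA_real_)
    }
    VA / denom
  })
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("%s: VA=%.4g VAY=%.4g VAL=%.4g Ve=%.4g (L=%d, Y=%d)  R=%.4f\n",
              x$trait, x$VA, x$VAY, x$VAL, x$Ve, x$L, x$Y, x$R))
  invisible(x)
}
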