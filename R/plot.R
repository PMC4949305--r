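## Diagnostic plotting, panelled by compartment like the model's figures.

#' Plot a postprandial trajectory
#'
#' Four panel groups: plasma (glucose, insulin, TAG, FFA), liver (glycogen,
#' FFA, TAG), muscle (glucose, glycogen, FFA, TAG) and the derived
#' observables (fractional glucose oxidation, adipose TAG clearance, AMP
#' marker).  An optional reference trajectory (typically healthy) is drawn
#' dashed for comparison.
#'
#' @param x `mf_trajectory`.
#' @param which Panel group(s); default all four.
#' @param reference Optional second `mf_trajectory` drawn dashed.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.mf_trajectory <- function(x, which = c("plasma", "liver", "muscle",
                                            "observables"),
                               reference = NULL, ...) {
  which <- match.arg(which, several.ok = TRUE)
  groups <- list(
    plasma = c("G_b", "T_b", "I", "A_b"),
    liver = c("Y_L", "A_L", "T_L"),
    muscle = c("G_m", "A_m", "Y_m", "T_m"),
    observables = c("frac_glucose_oxidation", "adipose_tag_clearance", "P"))
  labs <- c(G_b = "plasma glucose", T_b = "plasma TAG", I = "plasma insulin",
            A_b = "plasma FFA", Y_L = "hepatic glycogen",
            A_L = "hepatic FFA", T_L = "hepatic TAG",
            G_m = "muscle glucose", Y_m = "muscle glycogen",
            A_m = "muscle FFA", T_m = "muscle TAG", P = "AMP marker",
            frac_glucose_oxidation = "fractional glucose oxidation",
            adipose_tag_clearance = "adipose TAG clearance")
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  for (g in which) {
    vars <- groups[[g]]
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    for (v in vars) {
      ylim <- range(x[[v]], if (!is.null(reference)) reference[[v]])
      graphics::plot(x$t, x[[v]], type = "l", xlab = "time (h)",
                     ylab = labs[[v]], ylim = ylim,
                     main = if (v == vars[1])
                       paste0(g, if (!is.null(attr(x, "scenario")))
                         paste0(" - ", attr(x, "scenario"))) else "")
      if (!is.null(reference))
        graphics::lines(reference$t, reference[[v]], lty = 2)
    }
  }
  invisible(x)
}
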