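# The p-norm similarity index between folded surfaces compared on a
# common landmark-aligned disk domain.

#' p-norm similarity index between two fields on a common domain
#'
#' `s = 1 - ||I1 - I2|| _p / (2 m^{1/p})` for fields with values in
#' `[-1, 1]` on `m` common vertices; for `p = Inf` the norm is the
#' maximal absolute difference and `m^{1/p} = 1`. Since both fields are
#' bounded by 1 in absolute value, `0 <= s <= 1` always, with `s = 1`
#' iff the fields agree exactly.
#'
#' @param I1 reference field ([scalar_field()] or numeric).
#' @param I2_pulled comparison field already pulled back onto the
#'   reference vertices (see [pullback_field()]).
#' @param p 1, 2 or `Inf`.
#' @return the similarity index in `[0, 1]`.
#' @export
similarity_index <- function(I1, I2_pulled, p = 2) {
  a <- field_values(I1)
  b <- field_values(I2_pulled)
  if (length(a) != length(b))
    stop("field length mismatch: ", length(a), " vs ", length(b))
  m <- length(a)
  if (m < 1L) stop("empty fields")
  if (any(abs(a) > 1 + 1e-9) || any(abs(b) > 1 + 1e-9))
    stop("field values must lie in [-1, 1]")
  d <- abs(a - b)
  if (is.infinite(p)) {
    1 - max(d) / 2
  } else if (p == 1) {
    1 - sum(d) / (2 * m)
  } else if (p == 2) {
    1 - sqrt(sum(d^2)) / (2 * sqrt(m))
  } else {
    1 - sum(d^p)^(1 / p) / (2 * m^(1 / p))
  }
}

#' Full landmark-aligned surface comparison
#'
#' Runs the whole comparison chain between two simply connected open
#' surfaces: per-vertex curvature and shape index on both, disk
#' conformal parameterization of both, the landmark-matching
#' quasi-conformal map from the reference disk to the other, pull-back
#' of the comparison field onto the reference vertices, and the
#' similarity index for every requested p-norm and measure. The
#' comparison is asymmetric: `S1` is the reference domain.
#'
#' @param S1,S2 [tri_surface()] objects, disk-mappable.
#' @param lm1,lm2 corresponding landmark curve lists.
#' @param p_list p-norms to evaluate (subset of `c(1, 2, Inf)`).
#' @param measures `"si"` (shape index), `"htilde"` (rescaled mean
#'   curvature), or both.
#' @param landmark_tol landmark alignment tolerance in disk units.
#' @param umbilic_tol forwarded to [shape_index()].
#' @return a list of `similarity_report` objects (one per measure/p
#'   combination); see [similarity_table()] for a tabular view.
#' @export
compare_surfaces <- function(S1, S2, lm1, lm2, p_list = c(1, 2, Inf),
                             measures = c("si", "htilde"),
                             landmark_tol = 1e-3, umbilic_tol = 1e-12) {
  measures <- match.arg(measures, several.ok = TRUE)
  stage <- "curvature"
  reports <- tryCatch({
    cf1 <- vertex_curvatures(S1)
    cf2 <- vertex_curvatures(S2)
    fields1 <- measure_fields(cf1, measures, umbilic_tol)
    fields2 <- measure_fields(cf2, measures, umbilic_tol)
    stage <- "disk parameterization"
    D1 <- disk_conformal(S1)
    D2 <- disk_conformal(S2)
    stage <- "landmark matching"
    f12 <- landmark_qc_map(D1, D2, lm1, lm2, tol = landmark_tol,
                           faces1 = S1$faces)
    stage <- "pull-back and similarity"
    keep <- !cf1$boundary_mask
    m <- sum(keep)
    out <- list()
    for (msr in measures) {
      I1 <- fields1[[msr]]
      I2p <- field_values(pullback_field(fields2[[msr]], f12, S2$faces))
      d <- abs(I1[keep] - I2p[keep])
      for (p in p_list) {
        s <- similarity_index(I1[keep], I2p[keep], p)
        out[[length(out) + 1L]] <- structure(
          list(measure = msr, p = p, s = s, m = m,
               per_vertex_absdiff = scalar_field(d),
               provenance = list(landmark_residual = f12$residual,
                                 landmark_feasible = f12$feasible,
                                 max_abs_mu = max(Mod(f12$mu)),
                                 mean_abs_mu_D1 = D1$mean_abs_mu,
                                 mean_abs_mu_D2 = D2$mean_abs_mu,
                                 m_counts_boundary = FALSE)),
          class = "similarity_report")
      }
    }
    out
  }, error = function(e) {
    stop("surface comparison failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  reports
}

# Per-measure fields in [-1, 1] on all vertices; the rescaled mean
# curvature uses the interior (non-boundary) range and clamps boundary
# values into [-1, 1].
measure_fields <- function(cf, measures, umbilic_tol) {
  out <- list()
  if ("si" %in% measures)
    out$si <- as.numeric(shape_index(cf$H, cf$K_gauss, umbilic_tol))
  if ("htilde" %in% measures) {
    int <- !cf$boundary_mask
    rng <- range(cf$H[int])
    if (rng[2] <= rng[1]) stop("constant mean curvature field")
    out$htilde <- pmin(pmax(2 * (cf$H - rng[1]) / (rng[2] - rng[1]) - 1,
                            -1), 1)
  }
  out
}

#' Tabulate similarity reports
#'
#' @param reports list returned by [compare_surfaces()].
#' @return a data frame with one row per report (measure, p, s, m,
#'   landmark residual).
#' @export
similarity_table <- function(reports) {
  data.frame(
    measure = vapply(reports, function(r) r$measure, ""),
    p = vapply(reports, function(r) as.numeric(r$p), 0),
    s = vapply(reports, function(r) r$s, 0),
    m = vapply(reports, function(r) as.integer(r$m), 0L),
    landmark_residual = vapply(reports, function(r)
      r$provenance$landmark_residual, 0))
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("similarity_report:", x$measure, "p =", format(x$p), "s =",
      format(x$s, digits = 6), "over m =", x$m, "vertices\n")
  invisible(x)
}
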