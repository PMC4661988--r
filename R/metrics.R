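# Signal-to-error-ratio (SER) metrics and divergence statistics.
#
# SER treats the reference field (typically the PC-MRI measurement) as the
# "signal" and reports, in decibels,
#   SER = 10 log10( sum ||v_ref||^2 / sum ||v_est - v_ref||^2 ),
# overall and per component, with the sums restricted to a comparison mask
# (lumen voxels by default: summing over the full rectangular box would
# reward agreement on zero-padded background).

#' Signal-to-error ratio between velocity fields
#'
#' @param est list with cell-centered arrays `u`, `v`, `w` (e.g. from
#'   [stagger_to_centers()]) or an [mri_measurement()].
#' @param ref the reference ("signal") field, same format and shape.
#' @param mask logical array selecting compared voxels, or a [lumen_mask()]
#'   (its FLUID cells are used).  `NULL` compares everything.
#' @return object of class `ser_report` with `ser_u`, `ser_v`, `ser_w`,
#'   `ser_total` (dB; `Inf` sentinel for an exact match), component energies,
#'   and the voxel count `n`.
#' @export
ser <- function(est, ref, mask = NULL) {
  sel <- comparison_index(mask, dim(ref$u))
  if (length(sel) == 0) stop("empty comparison mask", call. = FALSE)
  if (!identical(dim(est$u), dim(ref$u)))
    stop("est/ref shape mismatch", call. = FALSE)
  num <- den <- 0
  comp_db <- c(u = NA_real_, v = NA_real_, w = NA_real_)
  energy <- c(u = NA_real_, v = NA_real_, w = NA_real_)
  for (comp in c("u", "v", "w")) {
    r <- ref[[comp]][sel]
    e <- est[[comp]][sel]
    s2 <- sum(r * r)
    d2 <- sum((e - r)^2)
    energy[comp] <- s2
    comp_db[comp] <- if (s2 == 0) NA_real_ else if (d2 == 0) Inf else
      10 * log10(s2 / d2)
    num <- num + s2
    den <- den + d2
  }
  if (num == 0) stop("reference field has zero energy on the mask", call. = FALSE)
  total <- if (den == 0) Inf else 10 * log10(num / den)
  structure(list(ser_u = comp_db[["u"]], ser_v = comp_db[["v"]],
                 ser_w = comp_db[["w"]], ser_total = total,
                 energy = energy, n = length(sel)),
            class = "ser_report")
}

comparison_index <- function(mask, dims) {
  if (is.null(mask)) return(seq_len(prod(dims)))
  if (inherits(mask, "lumen_mask")) return(which(unclass(mask) == MASK_FLUID))
  which(as.logical(mask))
}

#' @export
print.ser_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "  n/a" else if (is.infinite(v)) "  Inf"
    else sprintf("%6.2f", v)
  cat("<ser_report>  (dB, higher = closer to reference)\n")
  cat(sprintf("  SER_u %s  SER_v %s  SER_w %s  SER_total %s   [n = %d voxels]\n",
              fmt(x$ser_u), fmt(x$ser_v), fmt(x$ser_w), fmt(x$ser_total), x$n))
  invisible(x)
}

#' Pairwise component energy ratios
#'
#' `10 log10` ratios of the component energies of a reference field over the
#' comparison mask; quantifies how much stronger the through-plane (w)
#' component is than the in-plane ones.
#'
#' @inheritParams ser
#' @param ref reference field (list of arrays or [mri_measurement()]).
#' @return named numeric vector (dB) with `w_over_u`, `w_over_v`, `u_over_v`;
#'   `NA` sentinel where a component has zero energy.
#' @export
component_energy_ratio <- function(ref, mask = NULL) {
  sel <- comparison_index(mask, dim(ref$u))
  e <- vapply(c("u", "v", "w"), function(cc) sum(ref[[cc]][sel]^2), numeric(1))
  ratio <- function(a, b) if (e[[a]] == 0 || e[[b]] == 0) NA_real_ else
    10 * log10(e[[a]] / e[[b]])
  c(w_over_u = ratio("w", "u"), w_over_v = ratio("w", "v"),
    u_over_v = ratio("u", "v"))
}

#' Divergence statistics of a staggered field
#'
#' @param field a [staggered_field()].
#' @param grid its [grid_spec()].
#' @param mask comparison mask (see [ser()]); defaults to all cells.
#' @return list with `max`, `rms` and `n` over the masked cells, units 1/s.
#' @export
divergence_stats <- function(field, grid = field$grid, mask = NULL) {
  div <- divergence(field, grid)
  sel <- comparison_index(mask, dim(div))
  if (length(sel) == 0) stop("empty mask", call. = FALSE)
  d <- div[sel]
  list(max = max(abs(d)), rms = sqrt(mean(d * d)), n = length(d))
}

#' Serialize / restore an SER report
#'
#' JSON round-trip with an explicit `"Inf"` sentinel for infinite (exact
#' match) entries, so reports survive machine-readable storage losslessly.
#'
#' @param report a `ser_report`.
#' @param path file path.
#' @return `read_ser_report` returns the restored `ser_report`.
#' @export
write_ser_report <- function(report, path) {
  enc <- function(v) if (is.na(v)) "NA" else if (is.infinite(v)) "Inf" else v
  obj <- list(ser_u = enc(report$ser_u), ser_v = enc(report$ser_v),
              ser_w = enc(report$ser_w), ser_total = enc(report$ser_total),
              energy = as.list(report$energy), n = report$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ser_report
#' @export
read_ser_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(v) if (identical(v, "NA")) NA_real_ else
    if (identical(v, "Inf")) Inf else as.numeric(v)
  structure(list(ser_u = dec(obj$ser_u), ser_v = dec(obj$ser_v),
                 ser_w = dec(obj$ser_w), ser_total = dec(obj$ser_total),
                 energy = unlist(obj$energy), n = as.integer(obj$n)),
            class = "ser_report")
}

#' Format SER reports as a comparison table
#'
#' One column per solver mode, rows `SER_u` ... `SER_total` -- the layout
#' used to compare pure CFD against MRI-guided runs.
#'
#' @param reports named list of `ser_report`s (names become columns).
#' @return a data.frame with rownames `SER_u`, `SER_v`, `SER_w`, `SER_total`.
#' @export
ser_table <- function(reports) {
  stopifnot(length(reports) > 0)
  cols <- lapply(reports, function(r)
    c(SER_u = r$ser_u, SER_v = r$ser_v, SER_w = r$ser_w,
      SER_total = r$ser_total))
  as.data.frame(cols, check.names = FALSE)
}
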