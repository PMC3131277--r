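# Published morphometric measurements used as worked-example inputs and
# for internal-consistency checks of the reporting conventions.

#' Published 3D measurements of six selected microcracks
#'
#' Morphometry of six individual microcracks measured in human femoral-head
#' trabecular bone by synchrotron micro-CT at 1.4 um: two in-plane linear
#' cracks (L1, L2), a deflected linear crack (L3), a parallel-crack set
#' (P, average values), a pair of crossing twisted cracks (X) and a
#' cross-hatch network (CH). Columns: `Cr.Le`/`Cr.W` (um), `Cr.Th` (um),
#' `Cr.V` (1e-6 mm^3), `Cr.S` (1e-3 mm^2), `Tb.Th.lo` (um) and the local
#' trabecular shape. These printed values serve as inputs to consistency
#' checks (`Cr.S = Cr.V / Cr.Th`) and worked examples; they are not
#' recomputed from image data.
#'
#' @return data.frame with one row per crack.
#' @export
reference_cracks <- function() {
  data.frame(
    crack = c("L1", "L2", "P", "X", "CH", "L3"),
    sample = c(1, 2, 3, 2, 4, 5),
    cr_le_um = c(341, 149, 88, 269, 492, 300),
    cr_w_um = c(201, 78, 48, 132, 307, 190),
    cr_th_um = c(3.11, 2.91, 4.73, 3.11, 4.73, 2.91),
    cr_v_1e6mm3 = c(89.1, 14.85, 9.8, 60.96, 850.65, 80.73),
    cr_s_1e3mm2 = c(28.64, 5.10, 2.07, 19.60, 179.84, 27.74),
    tbthlo_um = c(308, 195, 232, 276, 231, 168),
    shape = c("Plate", "Junction", "Rod", "Junction", "Plate", "Rod"),
    stringsAsFactors = FALSE)
}

#' Published specimen-level morphometry of five trabecular bone specimens
#'
#' 3D and simulated-2D morphometry of five human femoral-head specimens
#' (2.8 x 2.8 mm cross-section, two merged scans): bone volume fraction,
#' SMI, lacunar density, microcrack counts and densities in 3D and from
#' eight 7 um virtual sections. Used for convention consistency checks
#' (e.g. that the pooled-bone-area 2D density convention reproduces the
#' printed `Cr.Dn 2D` from `Cr.N 2D` and `BV/TV 2D`).
#'
#' @return data.frame with one row per specimen.
#' @export
reference_specimens <- function() {
  data.frame(
    sample = 1:5,
    bvtv = c(0.22, 0.19, 0.16, 0.20, 0.12),
    bvtv_2d = c(0.20, 0.19, 0.20, 0.16, 0.10),
    smi = c(1.41, 1.73, 1.62, 2.20, 2.07),
    la_dn_1e3mm3 = c(15.68, 14.39, 12.44, 12.34, 8.01),
    cr_n = c(14, 14, 18, 28, 7),
    cr_n_2d = c(10, 7, 8, 19, 4),
    cr_dn_mm3 = c(3.42, 4.1, 4.91, 9.44, 3.11),
    cr_dn_2d_mm2 = c(0.76, 0.55, 0.60, 1.83, 0.58),
    cr_le_mean_um = c(206.57, 182.92, 204.94, 208.84, 164.14),
    cr_le_sd_um = c(124.43, 57.5, 140.65, 152.01, 90.92),
    cr_w_mean_um = c(111, 99.84, 119.77, 117.57, 95.57),
    cr_w_sd_um = c(71.19, 36.17, 91.29, 87.43, 66.73),
    cr_le_2d_mean_um = c(220.5, 130.8, 225.23, 238.15, 143.15),
    cr_le_2d_sd_um = c(101.88, 51.20, 135.36, 134.03, 19.45))
}
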