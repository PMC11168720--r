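#' Standard 10-20 scalp montage coordinates
#'
#' Schematic 2-D positions (head radius 1, nose towards +y, right ear +x) for
#' the 29-channel montage used throughout: Fp1/2, F3/4, C3/4, P3/4, O1/2,
#' F7/8, T3/4, T5/6, Fc1/2, Fc5/6, Cp1/2, Cp5/6, F9/10, Fz, Cz, Pz.
#' Positions are the usual equal-angle projection of the 10-20 system;
#' they are used for channel adjacency and topographic rendering only, so
#' arbitrary units suffice.
#'
#' @param labels optional character vector to subset/reorder; unknown labels
#'   are an error.
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
montage_1020 <- function(labels = NULL) {
  ring <- function(deg, r = 1) c(r * sinpi(deg / 180), r * cospi(deg / 180))
  pos <- rbind(
    Fp1 = ring(-18), Fp2 = ring(18),
    F7  = ring(-54), F8  = ring(54),
    T3  = ring(-90), T4  = ring(90),
    T5  = ring(-126), T6 = ring(126),
    O1  = ring(-162), O2 = ring(162),
    F9  = ring(-61, 1.1), F10 = ring(61, 1.1),
    F3  = c(-0.40, 0.52), F4 = c(0.40, 0.52),
    C3  = c(-0.50, 0.00), C4 = c(0.50, 0.00),
    P3  = c(-0.40, -0.52), P4 = c(0.40, -0.52),
    Fc1 = c(-0.22, 0.27), Fc2 = c(0.22, 0.27),
    Fc5 = c(-0.65, 0.28), Fc6 = c(0.65, 0.28),
    Cp1 = c(-0.22, -0.27), Cp2 = c(0.22, -0.27),
    Cp5 = c(-0.65, -0.28), Cp6 = c(0.65, -0.28),
    Fz  = c(0.00, 0.50), Cz = c(0.00, 0.00), Pz = c(0.00, -0.50))
  df <- data.frame(label = rownames(pos), x = pos[, 1], y = pos[, 2],
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    i <- match(labels, df$label)
    if (anyNA(i)) stopf("unknown montage label(s): %s",
                        paste(labels[is.na(i)], collapse = ", "))
    df <- df[i, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' The 29-channel label set of the reference montage
#' @export
montage_labels <- function() montage_1020()$label
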