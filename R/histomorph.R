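# Histological quantification: regeneration metrics from per-section
# measurements, AFOG trichrome colour decomposition of wound images, the
# Mef2/PCNA proliferation index, and region cell counts.

#' Build a per-section measurement table
#'
#' @param fish fish identifiers.
#' @param section section identifiers.
#' @param perimeter ventricle perimeter per section (micrometres).
#' @param open_length length of open compact myocardium per section
#'   (micrometres; must not exceed the perimeter).
#' @param wound_area,ventricle_area areas per section (square micrometres;
#'   wound must not exceed ventricle).
#' @return A validated data.frame of class \code{section_measurements}.
#' @export
section_measurements <- function(fish, section, perimeter, open_length,
                                 wound_area, ventricle_area) {
  df <- data.frame(fish = fish, section = section,
                   perimeter = perimeter, open_length = open_length,
                   wound_area = wound_area,
                   ventricle_area = ventricle_area,
                   stringsAsFactors = FALSE)
  stop_if_not(all(df$perimeter >= 0 & df$open_length >= 0 &
                    df$wound_area >= 0 & df$ventricle_area >= 0),
              "measurements must be >= 0")
  stop_if_not(all(df$open_length <= df$perimeter),
              "open length exceeds perimeter")
  stop_if_not(all(df$wound_area <= df$ventricle_area),
              "wound area exceeds ventricle area")
  class(df) <- c("section_measurements", "data.frame")
  df
}

# Largest per-fish value of a column, optionally for one fish.
fish_max <- function(measurements, col, fish) {
  sel <- measurements$fish == fish
  stop_if_not(any(sel), "no sections for fish '%s'", fish)
  max(measurements[[col]][sel])
}

#' Percentage of the myocardial wall still open
#'
#' For one fish, the largest open-myocardium length across its sections is
#' divided by the largest ventricle perimeter across its sections (maxima
#' taken independently, each over all sections) and multiplied by 100.
#' \code{matched_section = TRUE} instead uses the single section with the
#' largest perimeter for both numerator and denominator.
#'
#' @param measurements a \code{\link{section_measurements}} table.
#' @param fish fish identifier (defaults to the only fish present).
#' @param matched_section take numerator and denominator from the same
#'   section (the one with the largest perimeter) rather than independent
#'   maxima.
#' @return Percentage in [0,100].
#' @export
open_wall_percentage <- function(measurements,
                                 fish = unique(measurements$fish),
                                 matched_section = FALSE) {
  stop_if_not(length(fish) == 1, "give one fish id")
  sel <- measurements$fish == fish
  stop_if_not(any(sel), "no sections for fish '%s'", fish)
  if (matched_section) {
    i <- which(sel)[which.max(measurements$perimeter[sel])]
    per <- measurements$perimeter[i]
    op <- measurements$open_length[i]
  } else {
    per <- fish_max(measurements, "perimeter", fish)
    op <- fish_max(measurements, "open_length", fish)
  }
  stop_if_not(per > 0, "zero ventricle perimeter")
  100 * op / per
}

#' Wound area as a percentage of ventricle size
#'
#' For one fish, the largest wound area across sections divided by the
#' largest ventricle area across sections (independent maxima), times 100.
#'
#' @inheritParams open_wall_percentage
#' @return Percentage in [0,100].
#' @export
wound_area_percentage <- function(measurements,
                                  fish = unique(measurements$fish),
                                  matched_section = FALSE) {
  stop_if_not(length(fish) == 1, "give one fish id")
  sel <- measurements$fish == fish
  stop_if_not(any(sel), "no sections for fish '%s'", fish)
  if (matched_section) {
    i <- which(sel)[which.max(measurements$ventricle_area[sel])]
    va <- measurements$ventricle_area[i]
    wa <- measurements$wound_area[i]
  } else {
    va <- fish_max(measurements, "ventricle_area", fish)
    wa <- fish_max(measurements, "wound_area", fish)
  }
  stop_if_not(va > 0, "zero ventricle area")
  100 * wa / va
}

#' AFOG colour thresholds
#'
#' Channel thresholds on [0,1] applied identically to every image of an
#' experiment. The defaults (0.6/0.6) are arbitrary placeholders suited to
#' the synthetic palette; real experiments must calibrate their own values
#' and hold them fixed across hearts.
#'
#' @param red,blue thresholds in [0,1] for the red and blue channels.
#' @return An \code{afog_thresholds} list.
#' @export
afog_thresholds <- function(red = 0.6, blue = 0.6) {
  stop_if_not(red >= 0 && red <= 1 && blue >= 0 && blue <= 1,
              "thresholds must lie in [0,1]")
  structure(list(red = red, blue = blue), class = "afog_thresholds")
}

#' AFOG wound colour composition
#'
#' Within the wound mask, a pixel counts as red (fibrin) when its red
#' channel exceeds the red threshold and as blue (collagen) when its blue
#' channel exceeds the blue threshold; a pixel exceeding both is assigned
#' to the channel with the larger excess over its threshold (ties to red),
#' so the areas are disjoint. The orange (other/muscle) percentage is
#' 100 minus the red and blue percentages, so the three components sum to
#' exactly 100. Pixels outside the mask never contribute.
#'
#' @param image height x width x 3 RGB array in [0,1].
#' @param mask logical matrix of wound pixels (non-empty).
#' @param thresholds an \code{\link{afog_thresholds}}.
#' @return Named numeric: \code{red}, \code{blue}, \code{orange}
#'   percentages of the mask area.
#' @export
afog_composition <- function(image, mask, thresholds = afog_thresholds()) {
  stop_if_not(length(dim(image)) == 3 && dim(image)[3] == 3,
              "image must be height x width x 3")
  stop_if_not(all(dim(mask) == dim(image)[1:2]),
              "mask dimensions do not match image")
  area <- sum(mask)
  stop_if_not(area > 0, "empty mask")
  r <- image[, , 1][mask]
  b <- image[, , 3][mask]
  r_ex <- r - thresholds$red
  b_ex <- b - thresholds$blue
  is_red <- r_ex > 0 & (b_ex <= 0 | r_ex >= b_ex)
  is_blue <- b_ex > 0 & !is_red
  red_pct <- 100 * sum(is_red) / area
  blue_pct <- 100 * sum(is_blue) / area
  c(red = red_pct, blue = blue_pct, orange = 100 - red_pct - blue_pct)
}

#' Mef2/PCNA myocardial proliferation index
#'
#' For one fish, pools nuclei across its sections within the stated zone
#' (default the border zone: the cardiomyocytes closest to the wound) and
#' returns 100 x (Mef2+ and PCNA+) / Mef2+. A fish with fewer than three
#' sections triggers a warning, not an error. Set
#' \code{per_section = TRUE} to average per-section percentages instead of
#' pooling counts.
#'
#' @param nuclei data.frame with columns \code{fish}, \code{section},
#'   \code{zone}, \code{mef2}, \code{pcna} (see
#'   \code{\link{simulate_nuclei_table}}).
#' @param fish fish identifier (defaults to the only fish present).
#' @param zone \code{"border"} or \code{"remote"}.
#' @param per_section average of per-section percentages instead of pooled
#'   counts.
#' @return Percentage in [0,100].
#' @export
proliferation_index <- function(nuclei, fish = unique(nuclei$fish),
                                zone = "border", per_section = FALSE) {
  stop_if_not(length(fish) == 1, "give one fish id")
  sel <- nuclei$fish == fish & nuclei$zone == zone
  stop_if_not(any(sel), "no nuclei for fish '%s' in zone '%s'", fish, zone)
  sub <- nuclei[sel, ]
  n_sections <- length(unique(sub$section))
  if (n_sections < 3) {
    warning(sprintf("only %d section(s) for fish '%s'; at least 3 advised",
                    n_sections, fish))
  }
  stop_if_not(sum(sub$mef2) > 0, "zero Mef2+ nuclei")
  if (per_section) {
    pct <- tapply(seq_len(nrow(sub)), sub$section, function(i) {
      mm <- sub$mef2[i]
      if (sum(mm) == 0) return(NA_real_)
      100 * sum(sub$pcna[i] & mm) / sum(mm)
    })
    mean(pct, na.rm = TRUE)
  } else {
    100 * sum(sub$pcna & sub$mef2) / sum(sub$mef2)
  }
}

#' Count cells per region
#'
#' Cross-tabulates cells (typically double-positive calls) by tissue region
#' -- in the wound versus in the rest of the ventricle -- per sample.
#'
#' @param cells data.frame with a logical selection column (default
#'   \code{double}), a \code{region} column with values in \code{regions},
#'   and a \code{sample} column.
#' @param regions allowed region labels.
#' @param select name of the logical column marking the cells to count.
#' @return Integer matrix, regions x samples.
#' @export
count_region_cells <- function(cells, regions = c("wound", "ventricle"),
                               select = "double") {
  stop_if_not(all(c("region", "sample", select) %in% names(cells)),
              "cells must have columns region, sample, %s", select)
  bad <- setdiff(unique(cells$region), regions)
  stop_if_not(length(bad) == 0, "unknown region label: %s",
              paste(bad, collapse = ", "))
  sub <- cells[cells[[select]], , drop = FALSE]
  samp <- unique(cells$sample)
  out <- matrix(0L, length(regions), length(samp),
                dimnames = list(regions, samp))
  if (nrow(sub) > 0) {
    tab <- table(factor(sub$region, levels = regions),
                 factor(sub$sample, levels = samp))
    out[] <- as.integer(tab)
  }
  out
}
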