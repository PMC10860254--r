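## The Muenster 22-item cephalometric analysis.
##
## The measurement rules are a geometric reconstruction from the classical
## analyses the item list descends from (Downs, Ricketts, Rakosi, Steiner);
## each rule has been validated against the bundled expert reference
## recomputation, except the max./mand. length ratio, whose provenance status
## is `reconstructed` (see measurement_definitions()).

lm_pt <- function(points, name) {
  i <- match(name, points$landmark)
  if (is.na(i)) stop("missing landmark: ", name, call. = FALSE)
  c(points$x[i], points$y[i])
}

#' Definitions of the 22 cephalometric measurements
#'
#' One row per measurement with its unit, the landmarks it uses, a plain-text
#' geometric rule, and a provenance status: `verified` rules reproduce the
#' bundled expert reference values on image A; the `reconstructed` ratio item
#' does not reproduce its reference mean exactly and is flagged.
#'
#' @return A tibble with columns `measurement`, `unit`, `landmarks`, `rule`,
#'   `status`.
#' @export
measurement_definitions <- function() {
  def <- function(measurement, unit, landmarks, rule, status = "verified") {
    tibble::tibble(measurement = measurement, unit = unit,
                   landmarks = landmarks, rule = rule, status = status)
  }
  dplyr::bind_rows(
    def("Facial axis", "deg", "Ba N Pt Gnk",
        "obtuse angle between Ba-N and Pt-Gnk"),
    def("Facial depth", "deg", "N Po P Or",
        "acute angle between facial plane N-Po and Frankfurt horizontal"),
    def("SNB", "deg", "S N B", "angle S-N-B"),
    def("Mandibular plane", "deg", "hT Me P Or",
        "acute angle between mandibular plane hT-Me and Frankfurt horizontal"),
    def("Inner gonion angle", "deg", "DC Xi Pm", "angle DC-Xi-Pm"),
    def("Rel. mand. length", "mm", "Co Po", "distance Co-Po"),
    def("Maxillary position", "deg", "Ba N A", "angle Ba-N-A"),
    def("SNA", "deg", "S N A", "angle S-N-A"),
    def("Palatal plane", "deg", "P Or Spp Spa",
        "signed inclination of Frankfurt horizontal minus palatal plane Spp-Spa"),
    def("Rel. max. length", "mm", "Co A", "distance Co-A"),
    def("Lower facial height", "deg", "Spa Xi Pm", "angle Spa-Xi-Pm"),
    def("Convexity of point A", "mm", "A N Po",
        "anterior-positive distance of A to the facial plane N-Po"),
    def("Rel. max./mand. length", "ratio", "Co Po A",
        "|Co-Po| / |Co-A|", status = "reconstructed"),
    def("Lower incisor position", "mm", "LoIe A Po",
        "anterior-positive distance of LoIe to A-Po"),
    def("Lower incisor inclination", "deg", "LoIa LoIe A Po",
        "acute angle between lower incisor axis LoIa-LoIe and A-Po"),
    def("Upper incisor position", "mm", "UpIe A Po",
        "anterior-positive distance of UpIe to A-Po"),
    def("Upper incisor inclination", "deg", "UpIa UpIe A Po",
        "acute angle between upper incisor axis UpIa-UpIe and A-Po"),
    def("Inter incisor angle", "deg", "UpIa UpIe LoIa LoIe",
        "angle between the apex-to-edge vectors of the two incisors"),
    def("Vertical molar distance", "mm", "1UpMma Spp Spa",
        "inferior-positive distance of 1UpMma to the palatal plane Spp-Spa"),
    def("Sagittal molar distance", "mm", "1UpMdc Pt P Or",
        "projection of Pt-1UpMdc onto the Frankfurt horizontal"),
    def("Lower lip to E-line", "mm", "LoL Ap Pom",
        "anterior-positive distance of LoL to the esthetic line Ap-Pom"),
    def("Upper lip drape", "deg", "Sn UpL P Or",
        "acute angle between Sn-UpL and the Frankfurt horizontal")
  )
}

compute_items <- function(p, mm_per_px) {
  fh <- line_through(lm_pt(p, "P"), lm_pt(p, "Or"))     # cranial frame of reference
  fp <- line_through(lm_pt(p, "N"), lm_pt(p, "Po"))     # facial plane, cranial->caudal
  apo <- line_through(lm_pt(p, "A"), lm_pt(p, "Po"))    # dental base line, cranial->caudal
  pal <- line_through(lm_pt(p, "Spp"), lm_pt(p, "Spa")) # palatal plane, posterior->anterior
  eline <- line_through(lm_pt(p, "Ap"), lm_pt(p, "Pom"))
  dist <- function(a, b) sqrt(sum((lm_pt(p, a) - lm_pt(p, b))^2))
  vec_angle <- function(u, w) {
    co <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
    acos(min(1, max(-1, co))) * 180 / pi
  }
  up_axis <- lm_pt(p, "UpIe") - lm_pt(p, "UpIa")
  lo_axis <- lm_pt(p, "LoIe") - lm_pt(p, "LoIa")
  c(
    `Facial axis` = angle_between_lines(
      line_through(lm_pt(p, "Ba"), lm_pt(p, "N")),
      line_through(lm_pt(p, "Pt"), lm_pt(p, "Gnk")), "obtuse"),
    `Facial depth` = angle_between_lines(fp, fh, "acute"),
    `SNB` = angle_at_vertex(lm_pt(p, "S"), lm_pt(p, "N"), lm_pt(p, "B")),
    `Mandibular plane` = angle_between_lines(
      line_through(lm_pt(p, "hT"), lm_pt(p, "Me")), fh, "acute"),
    `Inner gonion angle` = angle_at_vertex(lm_pt(p, "DC"), lm_pt(p, "Xi"),
                                           lm_pt(p, "Pm")),
    `Rel. mand. length` = dist("Co", "Po") * mm_per_px,
    `Maxillary position` = angle_at_vertex(lm_pt(p, "Ba"), lm_pt(p, "N"),
                                           lm_pt(p, "A")),
    `SNA` = angle_at_vertex(lm_pt(p, "S"), lm_pt(p, "N"), lm_pt(p, "A")),
    `Palatal plane` = inclination_difference(fh, pal),
    `Rel. max. length` = dist("Co", "A") * mm_per_px,
    `Lower facial height` = angle_at_vertex(lm_pt(p, "Spa"), lm_pt(p, "Xi"),
                                            lm_pt(p, "Pm")),
    `Convexity of point A` = signed_point_line_distance(
      lm_pt(p, "A"), fp, "anterior_positive") * mm_per_px,
    `Rel. max./mand. length` = dist("Co", "Po") / dist("Co", "A"),
    `Lower incisor position` = signed_point_line_distance(
      lm_pt(p, "LoIe"), apo, "anterior_positive") * mm_per_px,
    `Lower incisor inclination` = angle_between_lines(
      ceph_line(lm_pt(p, "LoIa"), lo_axis), apo, "acute"),
    `Upper incisor position` = signed_point_line_distance(
      lm_pt(p, "UpIe"), apo, "anterior_positive") * mm_per_px,
    `Upper incisor inclination` = angle_between_lines(
      ceph_line(lm_pt(p, "UpIa"), up_axis), apo, "acute"),
    `Inter incisor angle` = vec_angle(up_axis, lo_axis),
    `Vertical molar distance` = signed_point_line_distance(
      lm_pt(p, "1UpMma"), pal, "inferior_positive") * mm_per_px,
    `Sagittal molar distance` = project_along(lm_pt(p, "1UpMdc"), lm_pt(p, "Pt"),
                                              fh) * mm_per_px,
    `Lower lip to E-line` = signed_point_line_distance(
      lm_pt(p, "LoL"), eline, "anterior_positive") * mm_per_px,
    `Upper lip drape` = angle_between_lines(
      line_through(lm_pt(p, "Sn"), lm_pt(p, "UpL")), fh, "acute")
  )
}

#' Compute the 22-item cephalometric analysis
#'
#' Evaluates all 22 measurements of the Muenster analysis on a complete
#' landmark set. Angle items are in degrees and independent of the pixel
#' spacing; distance items require `mm_per_px` to be expressed in mm — when
#' the spacing is unknown they are returned in pixels and flagged
#' (`calibrated = FALSE`).
#'
#' @param landmarks Landmark tibble (columns `landmark`, `x`, `y`) containing
#'   all 33 landmarks, or a `ceph_submission`.
#' @param mm_per_px Pixel spacing in mm/pixel (> 0), or `NULL` if unknown.
#' @return A tibble with columns `measurement`, `unit` (`"deg"`, `"mm"`,
#'   `"px"` or `"ratio"`), `value` and `calibrated`.
#' @seealso [calibrate_spacing()], [derive_constructed()],
#'   [measurement_definitions()]
#' @export
#' @examples
#' ref_a <- reference_landmarks() |> dplyr::filter(image == "A")
#' compute_analysis(ref_a, mm_per_px = 0.2043)
compute_analysis <- function(landmarks, mm_per_px = NULL) {
  if (inherits(landmarks, "ceph_submission")) landmarks <- landmarks$landmarks
  missing <- setdiff(landmark_names(), landmarks$landmark)
  if (length(missing)) {
    stop("missing landmarks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  calibrated <- !is.null(mm_per_px)
  if (calibrated && mm_per_px <= 0) {
    stop("mm_per_px must be positive", call. = FALSE)
  }
  vals <- compute_items(landmarks, if (calibrated) mm_per_px else 1)
  defs <- measurement_definitions()
  unit <- defs$unit
  unit[unit == "mm" & !calibrated] <- "px"
  tibble::tibble(
    measurement = defs$measurement,
    unit = unit,
    value = unname(vals[defs$measurement]),
    calibrated = calibrated | defs$unit != "mm"
  )
}

#' Calibrate the pixel spacing from one known measurement
#'
#' The radiograph's mm/pixel spacing is rarely exported with the landmark
#' coordinates. Every mm-valued item of the analysis is linear in the spacing,
#' so a single known millimetre value of one item recovers it.
#'
#' @param landmarks Complete landmark tibble or `ceph_submission`.
#' @param item Name of an mm-valued measurement, e.g.
#'   `"Convexity of point A"`.
#' @param known_mm The known value of that item in mm.
#' @return The spacing in mm/pixel.
#' @export
#' @examples
#' ref_a <- reference_landmarks() |> dplyr::filter(image == "A")
#' calibrate_spacing(ref_a, "Convexity of point A", 3.25)
calibrate_spacing <- function(landmarks, item, known_mm) {
  defs <- measurement_definitions()
  if (!item %in% defs$measurement[defs$unit == "mm"]) {
    stop("item must be one of the mm-valued measurements", call. = FALSE)
  }
  px <- compute_analysis(landmarks, mm_per_px = NULL)
  px_value <- px$value[px$measurement == item]
  if (abs(px_value) < .Machine$double.eps^0.5) {
    stop("item has zero pixel magnitude; cannot calibrate", call. = FALSE)
  }
  known_mm / px_value
}

#' Derive the constructed landmarks Gnk and Xi
#'
#' Gnk is the intersection of the mandibular plane (hT-Me) with the facial
#' plane (N-Po); Xi is the ramus midpoint located in the Frankfurt-aligned
#' frame from R1-R4 (see [construct_xi()]). Students place both manually; the
#' constructions serve to fill in absent placements and to audit manual ones.
#'
#' @param landmarks Landmark tibble containing the anatomical prerequisites
#'   (hT, Me, N, Po, P, Or, R1-R4).
#' @param prefer `"manual"` (default) keeps manual placements where present
#'   and only fills in absent ones; `"constructed"` replaces both.
#' @return The landmark tibble with Gnk and Xi present, with attribute
#'   `construction_report`: a tibble of manual vs constructed coordinates and
#'   their distance in pixels for auditing.
#' @export
derive_constructed <- function(landmarks, prefer = c("manual", "constructed")) {
  prefer <- match.arg(prefer)
  need <- c("hT", "Me", "N", "Po", "P", "Or", "R1", "R2", "R3", "R4")
  missing <- setdiff(need, landmarks$landmark)
  if (length(missing)) {
    stop("missing prerequisite landmarks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fh <- line_through(lm_pt(landmarks, "P"), lm_pt(landmarks, "Or"))
  constructed <- list(
    Gnk = line_intersection(
      line_through(lm_pt(landmarks, "hT"), lm_pt(landmarks, "Me")),
      line_through(lm_pt(landmarks, "N"), lm_pt(landmarks, "Po"))),
    Xi = construct_xi(lm_pt(landmarks, "R1"), lm_pt(landmarks, "R2"),
                      lm_pt(landmarks, "R3"), lm_pt(landmarks, "R4"), fh)
  )
  report <- purrr::map_dfr(names(constructed), function(nm) {
    manual <- if (nm %in% landmarks$landmark) lm_pt(landmarks, nm) else c(NA, NA)
    tibble::tibble(
      landmark = nm,
      manual_x = manual[1], manual_y = manual[2],
      constructed_x = constructed[[nm]][1],
      constructed_y = constructed[[nm]][2],
      distance_px = sqrt(sum((manual - constructed[[nm]])^2))
    )
  })
  out <- landmarks
  for (nm in names(constructed)) {
    present <- nm %in% out$landmark
    if (!present) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        landmark = nm, x = constructed[[nm]][1], y = constructed[[nm]][2]))
    } else if (prefer == "constructed") {
      i <- match(nm, out$landmark)
      out$x[i] <- constructed[[nm]][1]
      out$y[i] <- constructed[[nm]][2]
    }
  }
  attr(out, "construction_report") <- report
  out
}
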