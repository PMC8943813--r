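#' Write a trajectory to a human-readable XML file
#'
#' Header carries the ladder temperature, run control, force-field
#' parameters and a config hash; each frame stores the sampled step, the
#' energy breakdown, end-to-end distance, and the configuration (joint
#' positions and frame vectors).
#'
#' @param trajectory A `cg_trajectory` with stored configurations.
#' @param path Output path.
#' @param digits Coordinate precision (default 6 significant digits).
#' @return `path`, invisibly.
#' @export
write_trajectory_xml <- function(trajectory, path, digits = 6) {
  doc <- xml2::xml_new_root("trajectory")
  hdr <- xml2::xml_add_child(doc, "header")
  xml2::xml_set_attr(hdr, "temperature", trajectory$temperature)
  if (!is.null(trajectory$control)) {
    xml2::xml_set_attr(hdr, "n_steps", trajectory$control$n_steps)
    xml2::xml_set_attr(hdr, "seed", trajectory$control$seed)
  }
  if (!is.null(trajectory$ff))
    xml2::xml_set_attr(hdr, "config_hash",
                       config_hash(list(trajectory$ff, trajectory$control)))
  fmt <- function(m) paste(apply(m, 1, function(r)
    paste(signif(r, digits), collapse = " ")), collapse = "\n")
  for (i in seq_along(trajectory$configs)) {
    fr <- xml2::xml_add_child(doc, "frame")
    xml2::xml_set_attr(fr, "step", trajectory$samples$step[i])
    xml2::xml_set_attr(fr, "energy", trajectory$samples$total[i])
    xml2::xml_set_attr(fr, "end_to_end", trajectory$samples$end_to_end[i])
    xml2::xml_add_child(fr, "positions",
                        fmt(trajectory$configs[[i]]$pos))
    xml2::xml_add_child(fr, "frame_v", fmt(trajectory$configs[[i]]$v))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_xml()]
#'
#' @param path Path to the XML file.
#' @return A `cg_trajectory` (samples restricted to step, total energy and
#'   end-to-end distance).
#' @export
read_trajectory_xml <- function(path) {
  doc <- xml2::read_xml(path)
  hdr <- xml2::xml_find_first(doc, "header")
  frames <- xml2::xml_find_all(doc, "frame")
  parse_mat <- function(txt) {
    rows <- strsplit(trimws(strsplit(txt, "\n")[[1]]), " +")
    do.call(rbind, lapply(rows, as.numeric))
  }
  configs <- lapply(frames, function(fr) {
    structure(list(
      pos = parse_mat(xml2::xml_text(xml2::xml_find_first(fr, "positions"))),
      v = parse_mat(xml2::xml_text(xml2::xml_find_first(fr, "frame_v")))),
      class = "cg_configuration")
  })
  samples <- data.frame(
    step = as.numeric(xml2::xml_attr(frames, "step")),
    total = as.numeric(xml2::xml_attr(frames, "energy")),
    end_to_end = as.numeric(xml2::xml_attr(frames, "end_to_end")))
  structure(list(
    temperature = as.numeric(xml2::xml_attr(hdr, "temperature")),
    samples = samples, configs = configs),
    class = "cg_trajectory")
}
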