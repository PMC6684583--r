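#' Construct a co-IP channel design
#'
#' @param channel_id Character, unique isobaric-label identifiers (e.g.
#'   \code{"126"}, \code{"127N"}, ...).
#' @param sample_name Character, unique IP sample names.
#' @param antibody Character, antibody label per channel; IgG-control channels
#'   must carry an IgG-like label.
#' @param chemistry Character, \code{"agarose"} or \code{"magnetic"} per
#'   channel. Each chemistry present must have exactly one IgG control.
#' @param role Character, one of \code{"igg_control"}, \code{"bait"},
#'   \code{"unrelated_control"} per channel.
#' @return A validated [CoipDesign-class].
#' @examples
#' CoipDesign(channel_id = c("126", "127N", "127C"),
#'            sample_name = c("IgG.ag", "Bait.ag", "Unrel.ag"),
#'            antibody = c("IgG", "mAb1", "mAb2"),
#'            chemistry = rep("agarose", 3),
#'            role = c("igg_control", "bait", "unrelated_control"))
#' @export
CoipDesign <- function(channel_id, sample_name, antibody, chemistry, role) {
  ch <- S4Vectors::DataFrame(channel_id = as.character(channel_id),
                             sample_name = as.character(sample_name),
                             antibody = as.character(antibody),
                             chemistry = as.character(chemistry),
                             role = as.character(role))
  new("CoipDesign", channels = ch)
}

#' The standard 10-plex co-IP design
#'
#' Ten channels: one IgG control per bead chemistry, four bait IPs using
#' different antibody preparations against the same bait protein (split
#' across agarose and magnetic beads), and four IPs of unrelated proteins as
#' specificity controls. This mirrors the layout this package's scoring model
#' was built for; the mixed-antibody agarose bait is the conventional
#' reference sample for overlap statistics.
#'
#' @return A [CoipDesign-class] with 10 channels.
#' @examples
#' tenplexDesign()
#' @export
tenplexDesign <- function() {
  CoipDesign(
    channel_id  = c("126", "127N", "127C", "128N", "128C",
                    "129N", "129C", "130N", "130C", "131"),
    sample_name = c("IgG.agarose", "Bait.Mix.agarose", "Bait.C10.agarose",
                    "Unrel1.agarose", "Unrel2.agarose",
                    "IgG.magnetic", "Bait.Mix.magnetic", "Bait.2B22.magnetic",
                    "Unrel3.magnetic", "Unrel4.magnetic"),
    antibody    = c("IgG", "Mix", "C-10", "unrelated-1", "unrelated-2",
                    "IgG", "Mix", "2B22", "unrelated-3", "unrelated-4"),
    chemistry   = rep(c("agarose", "magnetic"), each = 5),
    role        = rep(c("igg_control", "bait", "bait",
                        "unrelated_control", "unrelated_control"), 2))
}

#' Read an experiment design from a YAML config
#'
#' The config is a key-value document with a \code{channels} list; each entry
#' has \code{channel_id}, \code{sample_name}, \code{antibody},
#' \code{chemistry} and \code{role}. All design invariants are checked and
#' violations raise errors naming the offending field.
#'
#' @param path Path to a YAML design file.
#' @return A validated [CoipDesign-class].
#' @seealso [writeDesign()], [CoipDesign()]
#' @export
readDesign <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$channels) || !length(doc$channels))
    stop("design file has no 'channels' entries: ", path)
  need <- c("channel_id", "sample_name", "antibody", "chemistry", "role")
  rows <- lapply(seq_along(doc$channels), function(i) {
    entry <- doc$channels[[i]]
    miss <- setdiff(need, names(entry))
    if (length(miss))
      stop(sprintf("channel entry %d is missing field(s): %s",
                   i, paste(miss, collapse = ", ")))
    lapply(entry[need], as.character)
  })
  CoipDesign(channel_id = vapply(rows, `[[`, "", "channel_id"),
             sample_name = vapply(rows, `[[`, "", "sample_name"),
             antibody = vapply(rows, `[[`, "", "antibody"),
             chemistry = vapply(rows, `[[`, "", "chemistry"),
             role = vapply(rows, `[[`, "", "role"))
}

#' Write an experiment design to YAML
#'
#' @param design A [CoipDesign-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "CoipDesign"))
  ch <- as.data.frame(design@channels)
  doc <- list(channels = lapply(seq_len(nrow(ch)), function(i) as.list(ch[i, ])))
  yaml::write_yaml(doc, path)
  invisible(path)
}
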