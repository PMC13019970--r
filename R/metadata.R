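#' Sample metadata for a longitudinal seeding study
#'
#' Per-sample study-design attributes. A sample's `week` is the END of its
#' 2-week passive collection window, on the biweekly grid; samples dated at
#' a seeding week were collected before the rug (re)deployment of that week,
#' so they are pre-seeding with respect to that event.
#'
#' Required columns:
#' \describe{
#'   \item{sample_id}{unique sample identifier}
#'   \item{home}{home label (or e.g. `"lab"` for blanks)}
#'   \item{sample_type}{`settled_dust`, `floor_dust`, `source_aliquot`,
#'     `outdoor`, or `control_blank`}
#'   \item{location}{`entrance`, `living_room`, `outdoor`, `floor`,
#'     `source`, or `none`}
#'   \item{height}{`IBZ` (30 cm), `ABZ` (150 cm), or `none`}
#'   \item{week}{integer on the 2-week grid; `NA` allowed for blanks only}
#'   \item{is_control_home}{logical}
#'   \item{kingdom}{`bacteria` or `fungi`}
#' }
#'
#' @param df a data frame with the columns above.
#' @return A validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "home", "sample_type", "location", "height",
           "week", "is_control_home", "kingdom")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  chk_enum <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad)) stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
  }
  chk_enum("sample_type", c("settled_dust", "floor_dust", "source_aliquot",
                            "outdoor", "control_blank"))
  chk_enum("location", c("entrance", "living_room", "outdoor", "floor",
                         "source", "none"))
  chk_enum("height", c("IBZ", "ABZ", "none"))
  chk_enum("kingdom", c("bacteria", "fungi"))
  df$week <- as.integer(df$week)
  wk_na <- is.na(df$week)
  if (any(wk_na & df$sample_type != "control_blank")) {
    stop("week may be NA only for control_blank samples")
  }
  if (any(df$week[!wk_na] %% 2L != 0L)) {
    stop("week values must lie on the biweekly grid (even integers)")
  }
  df$is_control_home <- as.logical(df$is_control_home)
  sd_rows <- df$sample_type == "settled_dust"
  if (any(sd_rows & !df$location %in% c("entrance", "living_room", "outdoor"))) {
    stop("settled_dust samples must have location entrance/living_room/outdoor")
  }
  indoor <- sd_rows & df$location %in% c("entrance", "living_room")
  if (any(indoor & !df$height %in% c("IBZ", "ABZ"))) {
    stop("indoor settled_dust samples must have height IBZ or ABZ")
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @param path TSV path with the exact metadata column names.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' @rdname sample_metadata
#' @param meta a `sample_metadata` object.
#' @export
write_sample_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "sample_metadata"))
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dust stratum label of each metadata row
#'
#' Collapses location x height x sample type into the five dust strata used
#' by the intervention statistics: `entrance_IBZ`, `entrance_ABZ`,
#' `LR_IBZ`, `LR_ABZ`, `floor`. Other samples get `NA`.
#'
#' @param meta a [sample_metadata()] data frame.
#' @return character vector of stratum labels (NA for non-dust samples).
#' @export
dust_stratum <- function(meta) {
  stopifnot(inherits(meta, "sample_metadata"))
  out <- rep(NA_character_, nrow(meta))
  sd <- meta$sample_type == "settled_dust" &
    meta$location %in% c("entrance", "living_room")
  loc <- ifelse(meta$location == "entrance", "entrance", "LR")
  out[sd] <- paste0(loc[sd], "_", meta$height[sd])
  out[meta$sample_type == "floor_dust"] <- "floor"
  out
}
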