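#' Region atlases
#'
#' A region atlas is the ordered list of cortical regions whose pairwise
#' fiber counts define the rows and columns of every connectivity matrix.
#' It is stored as a tibble with one row per region and columns `label`
#' (unique abbreviation such as `"PreCG-L"`), `hemisphere` (`"L"` or `"R"`)
#' and optionally `region` (full anatomical name). Left and right regions
#' pair by a shared stem: `PreCG-L` partners `PreCG-R`.
#'
#' @param labels Character vector of unique region abbreviations.
#' @param hemisphere Character vector of `"L"`/`"R"` tags, one per label.
#'   If missing, tags are parsed from a trailing `-L`/`-R` in each label.
#' @param region Optional character vector of full region names.
#'
#' @return A tibble of class `region_atlas` with columns `label`,
#'   `hemisphere` and (if given) `region`, in atlas order.
#' @examples
#' region_atlas(c("PreCG-L", "PreCG-R"))
#' @export
region_atlas <- function(labels, hemisphere = NULL, region = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("atlas labels must be unique", call. = FALSE)
  }
  if (length(labels) < 2) {
    stop("an atlas needs at least 2 regions", call. = FALSE)
  }
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(grepl("-L$", labels), "L",
                         ifelse(grepl("-R$", labels), "R", NA_character_))
  }
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != length(labels) || anyNA(hemisphere) ||
      !all(hemisphere %in% c("L", "R"))) {
    stop("every label needs exactly one hemisphere tag in {L, R}",
         call. = FALSE)
  }
  out <- tibble::tibble(label = labels, hemisphere = hemisphere)
  if (!is.null(region)) out$region <- as.character(region)
  class(out) <- c("region_atlas", class(out))
  out
}

#' Read a region atlas from a delimited file
#'
#' Expects at least two columns, `label` and `hemisphere` (tab- or
#' comma-separated, header row required).
#'
#' @param path Path to the atlas file.
#' @return A [region_atlas()] tibble.
#' @export
read_atlas <- function(path) {
  tab <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("label", "hemisphere") %in% names(tab))) {
    stop("atlas file must have columns 'label' and 'hemisphere'",
         call. = FALSE)
  }
  region_atlas(tab$label, tab$hemisphere,
               region = if ("region" %in% names(tab)) tab$region)
}

#' The 78-region cortical AAL atlas
#'
#' The cortical parcellation used throughout developmental connectomics:
#' 78 regions of the Automated Anatomical Labeling template (39 per
#' hemisphere; subcortical and cerebellar regions excluded), in
#' left/right-interleaved order.
#'
#' @return A [region_atlas()] tibble with 78 rows.
#' @examples
#' nrow(aal78_atlas())
#' @export
aal78_atlas <- function() {
  read_atlas(system.file("extdata", "aal78_atlas.tsv", package = "fibernet",
                         mustWork = TRUE))
}

#' Pair left and right regions by label stem
#'
#' @param atlas A [region_atlas()].
#' @return A tibble with columns `stem`, `left`, `right` giving, for each
#'   stem, the atlas indices of the left and right partner regions.
#'   Errors if any region lacks a contralateral partner.
#' @export
atlas_pairs <- function(atlas) {
  stem <- sub("-[LR]$", "", atlas$label)
  left <- which(atlas$hemisphere == "L")
  right <- which(atlas$hemisphere == "R")
  rs <- stem[right][match(stem[left], stem[right])]
  unmatched <- c(atlas$label[left][is.na(rs)],
                 atlas$label[right][!(stem[right] %in% stem[left])])
  if (length(unmatched) > 0) {
    stop("unpaired region labels: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  partner <- right[match(stem[left], stem[right])]
  tibble::tibble(stem = stem[left], left = left, right = partner)
}
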