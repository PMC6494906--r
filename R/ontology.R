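#' Anatomical ontology maps
#'
#' An `OntologyMap` binds substructure codes to their parent structure, major
#' region and ontogenic (embryonic) origin, plus a rostro-caudal rank used to
#' order tabular output and a white-matter flag used to exclude negligible
#' expression samples from microarray runs.
#'
#' @param entries data.frame with columns `substructure`, `structure`,
#'   `major_region`, `origin`, `rank` (integer, unique), `white_matter`
#'   (logical).
#' @return An object of class `OntologyMap` (a data.frame).
#' @export
ontology_map <- function(entries) {
  need <- c("substructure", "structure", "major_region", "origin",
            "rank", "white_matter")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("ontology missing columns: ", paste(miss, collapse = ", "))
  entries <- as.data.frame(entries)[, need]
  if (anyDuplicated(entries$substructure))
    stop("duplicate substructure codes in ontology")
  if (anyDuplicated(entries$rank))
    stop("rostro-caudal ranks must be unique")
  # every structure maps to exactly one major region
  mr <- tapply(entries$major_region, entries$structure,
               function(v) length(unique(v)))
  if (any(mr > 1))
    stop("structure mapped to more than one major region: ",
         paste(names(mr)[mr > 1], collapse = ", "))
  class(entries) <- c("OntologyMap", "data.frame")
  entries
}

# Structure -> (major region, origin, substructure count) for the synthetic
# default map. Counts sum to 111 grey-matter substructures; the Allen
# structure abbreviations are the ones used in the atlas figure legends.
.ontology_layout <- function() {
  list(
    # structure, major_region, origin, n, named substructures (filled first)
    list("FL",    "cerebral_cortex",  "telencephalon", 12, c("FrOp")),
    list("Ins",   "cerebral_cortex",  "telencephalon",  4, character()),
    list("CgG",   "cerebral_cortex",  "telencephalon",  4, character()),
    list("HiF",   "cerebral_cortex",  "telencephalon",  7,
         c("DG", "CA1", "CA2", "CA3", "CA4", "S")),
    list("PHG",   "cerebral_cortex",  "telencephalon",  3, character()),
    list("OL",    "cerebral_cortex",  "telencephalon",  6, c("Cun.str")),
    list("PL",    "cerebral_cortex",  "telencephalon",  6, character()),
    list("TL",    "cerebral_cortex",  "telencephalon",  7, character()),
    list("Amg",   "cerebral_nuclei",  "telencephalon",  6, c("CeA")),
    list("GP",    "cerebral_nuclei",  "telencephalon",  3, character()),
    list("Str",   "cerebral_nuclei",  "telencephalon",  5, c("Acb")),
    list("Cl",    "cerebral_nuclei",  "telencephalon",  1, character()),
    list("Hy",    "diencephalon",     "diencephalon",   6, c("PrOR")),
    list("SbT",   "diencephalon",     "diencephalon",   2, character()),
    list("DT",    "diencephalon",     "diencephalon",   8, c("ILr")),
    list("VT",    "diencephalon",     "diencephalon",   2, character()),
    list("MES",   "mesencephalon",    "mesencephalon",  6, c("RN")),
    list("CbCx",  "cerebellum",       "metencephalon",  8,
         c("PV.V", "PV.VIIB")),
    list("CbN",   "cerebellum",       "metencephalon",  2, character()),
    list("Bpons", "pons",             "metencephalon",  3, character()),
    list("PTg",   "pons",             "metencephalon",  5, character()),
    list("MY",    "myelencephalon",   "myelencephalon", 5, c("IO"))
  )
}

#' Build the default synthetic ontology
#'
#' Constructs a stand-in for the atlas anatomical hierarchy: 111 grey-matter
#' substructures spread over 22 structures and 7 major regions (plus one
#' white-matter structure carrying the exclusion flag). Substructure codes
#' are `<structure>.<name>`; a handful of real atlas substructure names
#' (DG, CeA, Acb, PrOR, PV.V, FrOp, ...) are included so that enrichment and
#' reference-structure examples read naturally. This map is synthetic: it
#' reproduces the shape of the atlas ontology, not its actual contents.
#'
#' @return An `OntologyMap` with 113 rows (111 grey matter + 2 white matter).
#' @export
build_default_ontology <- function() {
  rows <- list()
  rank <- 0L
  for (st in .ontology_layout()) {
    code <- st[[1]]; region <- st[[2]]; origin <- st[[3]]
    n <- st[[4]]; named <- st[[5]]
    subs <- c(named, if (n > length(named))
      paste0("s", seq_len(n - length(named))))
    for (s in subs) {
      rank <- rank + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        substructure = paste0(code, ".", s), structure = code,
        major_region = region, origin = origin, rank = rank,
        white_matter = FALSE)
    }
  }
  for (s in c("cc", "ic")) {  # corpus callosum, internal capsule
    rank <- rank + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      substructure = paste0("WM.", s), structure = "WM",
      major_region = "white_matter", origin = "telencephalon",
      rank = rank, white_matter = TRUE)
  }
  ontology_map(do.call(rbind, rows))
}

#' Load the packaged synthetic ontology JSON
#'
#' Reads `inst/extdata/ontology_gabaa_synthetic.json`, the serialized form of
#' [build_default_ontology()].
#'
#' @param path optional path to an ontology JSON file; defaults to the
#'   packaged synthetic map.
#' @return An `OntologyMap`.
#' @export
default_ontology <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ontology_gabaa_synthetic.json",
                        package = "pentalayout")
  read_ontology(path)
}

#' Read an ontology map from JSON
#'
#' The JSON is an array of objects with fields `substructure`, `structure`,
#' `major_region`, `origin`, `rank`, `white_matter`.
#'
#' @param path path to a JSON file.
#' @return An `OntologyMap`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  df <- jsonlite::fromJSON(path)
  df$rank <- as.integer(df$rank)
  df$white_matter <- as.logical(df$white_matter)
  ontology_map(df)
}

#' Write an ontology map to JSON
#'
#' @param ontology an `OntologyMap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  df <- as.data.frame(unclass(ontology))
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Resolve substructure codes against an ontology
#'
#' @param codes character vector of substructure codes.
#' @param ontology an `OntologyMap`.
#' @return The matching ontology rows, in the order of `codes`.
#' @keywords internal
ontology_lookup <- function(codes, ontology) {
  idx <- match(codes, ontology$substructure)
  if (anyNA(idx))
    stop("unknown substructure code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  ontology[idx, , drop = FALSE]
}
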