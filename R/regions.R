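# Residue region sets (extracellular/intracellular loops, binding site,
# G-protein interface) and the shipped A2AR fixture.

#' Construct a region set
#'
#' @param name one of `"extracellular"`, `"intracellular"`, `"binding_site"`,
#'   `"gprotein_interface"`, `"ec_region"`, or `"custom"`.
#' @param residues integer vector of residue ids; sets may overlap.
#' @param loops optional named list of residue-id vectors partitioning the
#'   set into loops (used for per-loop entropy subtotals).
#' @return object of class `region_set`.
#' @export
region_set <- function(name, residues, loops = NULL) {
  known <- c("extracellular", "intracellular", "binding_site",
             "gprotein_interface", "ec_region", "custom")
  if (!name %in% known) name <- "custom"
  residues <- sort(unique(as.integer(residues)))
  if (!length(residues)) stopf("region set is empty")
  structure(list(name = name, residues = residues, loops = loops),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s: %d residues\n", x$name, length(x$residues)))
  invisible(x)
}

# Expand entries like "I64-L78" or "R102" (1-letter aa + author number,
# ranges inclusive on both ends) into integer residue ids.
expand_region_entry <- function(entry) {
  parts <- strsplit(trimws(entry), "-")[[1]]
  nums <- as.integer(gsub("[A-Za-z]", "", parts))
  if (anyNA(nums)) stopf("cannot parse region entry '%s'", entry)
  if (length(nums) == 1) return(nums)
  if (length(nums) != 2 || nums[2] < nums[1])
    stopf("bad region range '%s'", entry)
  seq(nums[1], nums[2])
}

#' Load the shipped receptor region definitions
#'
#' Returns the adenosine A2A receptor region sets used throughout the
#' package: the extracellular and intracellular loop regions (each loop
#' including the top/bottom two helical turns), the orthosteric binding-site
#' residues, the G-protein interface residues, and the broader extracellular
#' region used as pathway sources. Residue numbering is 1-based author
#' numbering; ranges are inclusive on both ends.
#'
#' @param receptor receptor name; only `"A2AR"` ships with the package.
#' @return named list of [region_set()] objects with elements
#'   `extracellular`, `intracellular`, `binding_site`, `gprotein_interface`,
#'   `ec_region`.
#' @export
load_region_fixture <- function(receptor = "A2AR") {
  if (!identical(toupper(receptor), "A2AR"))
    stopf("unknown receptor '%s'; shipped fixtures: A2AR", receptor)
  path <- system.file("extdata", "a2ar_regions.tsv", package = "gpcrdyn")
  if (path == "") path <- file.path("inst", "extdata", "a2ar_regions.tsv")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  out <- list()
  for (rg in unique(tab$region)) {
    entries <- tab$entry[tab$region == rg]
    ids <- lapply(entries, expand_region_entry)
    loops <- NULL
    if (rg %in% c("extracellular", "intracellular"))
      loops <- setNames(ids, sprintf("loop%d", seq_along(ids)))
    out[[rg]] <- region_set(rg, unlist(ids), loops = loops)
  }
  out
}

# Check that every region residue exists in the topology.
check_region_in_topology <- function(region, top) {
  miss <- setdiff(region$residues, top$residues$resid)
  if (length(miss))
    stopf("region '%s' references residues absent from topology: %s",
          region$name, paste(miss, collapse = ", "))
  invisible(TRUE)
}
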