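#' Default NSAID drug catalogue
#'
#' A catalogue of NSAID substances used throughout the package: ATC-style
#' code (`M01A` prefix), human-readable name, class (`coxib` for the five
#' COX-2 selective inhibitors celecoxib, etoricoxib, lumiracoxib, rofecoxib
#' and valdecoxib; `tNSAID` for all traditional, i.e. non-coxib, NSAIDs),
#' DDD per dispensed unit, and a typical pack size in DDD used by the
#' synthetic claims generator.
#'
#' @return A `data.table` with columns `substance` (ATC code), `name`,
#'   `class`, `ddd_per_unit`, `pack_ddd`.
#' @export
#' @examples
#' default_drug_catalogue()
default_drug_catalogue <- function() {
  data.table(
    substance = c("M01AH01", "M01AH02", "M01AH03", "M01AH05", "M01AH06",
                  "M01AB05", "M01AB01", "M01AB15", "M01AE01", "M01AE02",
                  "M01AE03", "M01AC01", "M01AC06", "M01AX17"),
    name = c("celecoxib", "rofecoxib", "valdecoxib", "etoricoxib",
             "lumiracoxib",
             "diclofenac", "indometacin", "ketorolac", "ibuprofen",
             "naproxen", "ketoprofen", "piroxicam", "meloxicam",
             "nimesulide"),
    class = c(rep("coxib", 5L), rep("tNSAID", 9L)),
    ddd_per_unit = 1,
    pack_ddd = 30
  )
}

#' The five COX-2 selective inhibitors
#'
#' @return character vector of substance names classified as coxibs.
#' @export
coxib_names <- function() {
  c("celecoxib", "etoricoxib", "lumiracoxib", "rofecoxib", "valdecoxib")
}

#' Classify a substance as coxib or traditional NSAID
#'
#' Class is determined by membership in the five-member coxib list; every
#' other NSAID in the catalogue is a traditional (non-coxib) NSAID.
#'
#' @param substance character vector of ATC codes or substance names.
#' @param catalogue drug catalogue as from [default_drug_catalogue()].
#' @return character vector, `"coxib"` or `"tNSAID"`.
#' @export
#' @examples
#' drug_class_of("rofecoxib")
#' drug_class_of("M01AB05")   # diclofenac
drug_class_of <- function(substance, catalogue = default_drug_catalogue()) {
  i <- match(substance, catalogue$substance)
  j <- match(substance, catalogue$name)
  i[is.na(i)] <- j[is.na(i)]
  if (anyNA(i)) {
    stop("unknown substance(s): ",
         paste(unique(substance[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  ifelse(catalogue$name[i] %in% coxib_names(), "coxib", "tNSAID")
}
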