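#' Synonymous codon families of a genetic code
#'
#' Builds the codon-family structure used throughout the package: the 61 sense
#' codons partitioned into synonymous families, each with a fixed reference
#' codon (the alphabetically last member, whose mutation-bias and selection
#' coefficients are pinned at zero).
#'
#' Serine is always split into two families, `Ser4` (TCA/TCC/TCG/TCT) and
#' `Ser2` (AGC/AGT): under weak mutation with a fixed amino-acid sequence,
#' exchanges between the two serine codon groups would require passing through
#' a non-serine intermediate, so they are modelled as separate families.
#'
#' For yeasts of the CTG clade, which translate CTG as serine rather than
#' leucine, `code_name = "ctg_ser"` removes CTG from the leucine family and
#' treats it as a synonym-less singleton (like ATG and TGG).
#'
#' @param code_name `"standard"` or `"ctg_ser"`.
#' @return An object of class `genetic_code`: a list with elements
#'   `code_name`, `codons` (the 61 sense codons, alphabetical), `families`
#'   (named list of `family_id`, `codons`, `reference`, `size`),
#'   `codon_to_family` (named character over the sense codons), `stop_codons`,
#'   and `n_free` (number of free coefficients per parameter type,
#'   \eqn{\sum_{aa} (n_{aa} - 1)}: 40 for the standard code, 39 for `ctg_ser`).
#' @examples
#' gc <- genetic_code()
#' gc$n_free
#' gc$families$Ser2
#' @export
genetic_code <- function(code_name = c("standard", "ctg_ser")) {
  code_name <- match.arg(code_name)
  tab <- Biostrings::GENETIC_CODE
  stop_codons <- names(tab)[tab == "*"]
  sense <- sort(names(tab)[tab != "*"])

  aa <- tab[sense]
  fam_of <- vapply(sense, function(cod) {
    a <- unname(aa[cod])
    if (a == "S") {
      if (substr(cod, 1, 2) == "TC") "Ser4" else "Ser2"
    } else {
      aa_three_letter(a)
    }
  }, character(1))
  if (code_name == "ctg_ser") {
    fam_of["CTG"] <- "SerCTG"
  }

  fams <- lapply(split(sense, fam_of), function(cods) {
    cods <- sort(cods)
    list(
      family_id = unname(fam_of[cods[1]]),
      codons = cods,
      reference = cods[length(cods)],
      size = length(cods)
    )
  })
  fams <- fams[order(names(fams))]

  structure(
    list(
      code_name = code_name,
      codons = sense,
      families = fams,
      codon_to_family = fam_of,
      stop_codons = stop_codons,
      n_free = sum(vapply(fams, function(f) f$size - 1L, integer(1)))
    ),
    class = "genetic_code"
  )
}

aa_three_letter <- function(a) {
  map <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val"
  )
  unname(map[a])
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(
    "<genetic_code> ", x$code_name, ": ", length(x$codons), " sense codons, ",
    length(x$families), " families, ", x$n_free, " free coefficients\n",
    sep = ""
  )
  invisible(x)
}

# Families that carry information about codon preference (>= 2 synonyms).
multi_codon_families <- function(gcode) {
  Filter(function(f) f$size >= 2L, gcode$families)
}

# Column-index bookkeeping for the likelihood kernels: for each multi-codon
# family, the (1-based) columns of the 61-codon count matrix belonging to its
# members, its reference column, and the non-reference columns.
family_index <- function(gcode) {
  lapply(multi_codon_families(gcode), function(f) {
    cols <- match(f$codons, gcode$codons)
    ref <- match(f$reference, gcode$codons)
    list(
      family_id = f$family_id,
      codons = f$codons,
      cols = cols,
      ref_col = ref,
      nonref_cols = setdiff(cols, ref),
      nonref_codons = setdiff(f$codons, f$reference)
    )
  })
}
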