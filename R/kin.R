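# Kin types as feature bundles, kin-code parsing, subdomain inventories,
# and the extension-counting rule that turns a term table into a
# category-system size.

# Referent letters: sex and generation offset of a single genealogical step.
KIN_LETTERS <- list(
  F = list(sex = "male",        gen = +1L),  # father
  M = list(sex = "female",      gen = +1L),  # mother
  B = list(sex = "male",        gen = 0L),   # brother
  Z = list(sex = "female",      gen = 0L),   # sister
  G = list(sex = "unspecified", gen = 0L),   # sibling (underspecified)
  S = list(sex = "male",        gen = -1L),  # son
  D = list(sex = "female",      gen = -1L),  # daughter
  C = list(sex = "unspecified", gen = -1L)   # child (underspecified)
)

#' Parse a kin-type code
#'
#' Kin codes follow the compact genealogical grammar used by kin-term
#' databases: an optional leading lowercase `m`/`f` gives the speaker's sex,
#' and the remainder is a chain of genealogical steps, each an uppercase
#' letter (`F` father, `M` mother, `B` brother, `Z` sister, `G` sibling,
#' `S` son, `D` daughter, `C` child) optionally preceded by lowercase
#' `e`/`y` (elder/younger). So `meB` is a male speaker's elder brother,
#' `fyZ` a female speaker's younger sister, `FF` the father's father, and
#' `MZ` the mother's sister. Unknown codes are rejected with an error.
#'
#' @param code a kin-type code string
#' @return an object of class `symcat_kin_type`: list with `code`,
#'   `speaker_sex`, `referent_sex`, `relative_age`, `generation`
#'   (integer offset from ego), and `connecting_relative_sex`
#'   (`"paternal"`, `"maternal"` or `"unspecified"`; set from the first
#'   step of a chain of length two or more)
#' @examples
#' parse_kin_type("meB")$relative_age   # "elder"
#' parse_kin_type("FF")$generation      # 2
#' @export
parse_kin_type <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!grepl("^[mf]?([ey]?[A-Z])+$", code)) {
    stop("unknown kin code: '", code, "'", call. = FALSE)
  }
  rest <- code
  speaker_sex <- "unspecified"
  if (grepl("^[mf]", rest)) {
    speaker_sex <- if (substr(rest, 1, 1) == "m") "male" else "female"
    rest <- substr(rest, 2, nchar(rest))
  }
  segs <- regmatches(rest, gregexpr("[ey]?[A-Z]", rest))[[1]]
  steps <- lapply(segs, function(seg) {
    age <- "unspecified"
    if (grepl("^[ey]", seg)) {
      age <- if (substr(seg, 1, 1) == "e") "elder" else "younger"
      seg <- substr(seg, 2, 2)
    }
    info <- KIN_LETTERS[[seg]]
    if (is.null(info)) {
      stop("unknown kin code: '", code, "' (letter '", seg, "')",
           call. = FALSE)
    }
    c(info, list(age = age))
  })

  last <- steps[[length(steps)]]
  connecting <- "unspecified"
  if (length(steps) >= 2L) {
    first_sex <- steps[[1]]$sex
    connecting <- switch(first_sex,
                         male = "paternal", female = "maternal",
                         "unspecified")
  }
  structure(
    list(code = code,
         speaker_sex = speaker_sex,
         referent_sex = last$sex,
         relative_age = last$age,
         generation = sum(vapply(steps, function(s) s$gen, integer(1))),
         connecting_relative_sex = connecting),
    class = "symcat_kin_type"
  )
}

#' Format a kin type back to its code string
#' @param kt a `symcat_kin_type`
#' @return the code string (round-trips through [parse_kin_type()])
#' @export
format_kin_type <- function(kt) kt$code

#' @export
print.symcat_kin_type <- function(x, ...) {
  cat("<kin type", x$code, "| speaker", x$speaker_sex, "| referent",
      x$referent_sex, "| age", x$relative_age, "| generation",
      sprintf("%+d", x$generation), "| line", x$connecting_relative_sex,
      ">\n")
  invisible(x)
}

#' Kin-type inventory for a kinship subdomain
#'
#' Returns the kin types over which term extensions are counted for one of
#' the six kinship subdomains. The sibling inventory is fixed: the 12 types
#' `mB, mZ, meB, meZ, myB, myZ` and their female-speaker analogues; the
#' underspecified `mG` and `fG` are deliberately excluded because the
#' counting rule is defined over proper subsets of the subdomain. The five
#' other inventories ship as editable configuration
#' (`inst/extdata/kin_inventories.csv`) with package-default reconstructions
#' clearly marked as such; supply `inventory_file` to override them.
#'
#' @param subdomain one of `"siblings"`, `"parents_siblings"`,
#'   `"grandparents"`, `"grandchildren"`, `"nieces_nephews"`, `"cousins"`
#' @param inventory_file optional CSV with columns `subdomain, code`
#'   overriding the shipped defaults (the sibling inventory cannot be
#'   overridden)
#' @return character vector of kin codes (each valid per
#'   [parse_kin_type()])
#' @export
subdomain_kin_types <- function(subdomain, inventory_file = NULL) {
  valid <- c("siblings", "parents_siblings", "grandparents",
             "grandchildren", "nieces_nephews", "cousins")
  if (!subdomain %in% valid) {
    stop("unknown subdomain '", subdomain, "'; expected one of: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  if (subdomain == "siblings") {
    codes <- c("mB", "mZ", "meB", "meZ", "myB", "myZ",
               "fB", "fZ", "feB", "feZ", "fyB", "fyZ")
  } else {
    path <- inventory_file %||%
      system.file("extdata", "kin_inventories.csv", package = "symcat")
    inv <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    codes <- inv$code[inv$subdomain == subdomain]
    if (length(codes) == 0) {
      stop("inventory file has no rows for subdomain '", subdomain, "'",
           call. = FALSE)
    }
  }
  invisible(lapply(codes, parse_kin_type))  # validates every code
  codes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count the categories of a kin-term system
#'
#' Applies the extension-counting rule: restrict every term's extension to
#' the subdomain's kin-type inventory, drop terms whose restricted extension
#' is empty, and count the *distinct* extension sets. Terms with identical
#' extensions (synonyms, orthographic variants) count as a single category;
#' overlapping extensions (e.g. *brother* alongside *younger brother*) count
#' separately, so overlapping and hierarchical systems are supported.
#'
#' @param terms a data frame with columns `language`, `term`, `kin_type`
#'   (one row per term x kin-type pair), all rows from a single language
#' @param subdomain passed to [subdomain_kin_types()]
#' @param inventory optional character vector of kin codes overriding the
#'   subdomain inventory
#' @return integer: the number of categories (distinct restricted
#'   extensions)
#' @examples
#' tab <- tibble::tibble(
#'   language = "English",
#'   term = rep(c("brother", "sister"), each = 6),
#'   kin_type = c("mB", "meB", "myB", "fB", "feB", "fyB",
#'                "mZ", "meZ", "myZ", "fZ", "feZ", "fyZ")
#' )
#' extract_category_system(tab, "siblings")  # 2
#' @export
extract_category_system <- function(terms, subdomain = "siblings",
                                    inventory = NULL) {
  stopifnot(all(c("language", "term", "kin_type") %in% names(terms)))
  if (nrow(terms) == 0) {
    stop("`terms` is empty", call. = FALSE)
  }
  if (length(unique(terms$language)) != 1L) {
    stop("all rows must come from a single language; got: ",
         paste(unique(terms$language), collapse = ", "), call. = FALSE)
  }
  inventory <- inventory %||% subdomain_kin_types(subdomain)
  kept <- terms[terms$kin_type %in% inventory, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("language '", terms$language[1], "' has no terms whose extension ",
         "meets the '", subdomain, "' inventory", call. = FALSE)
  }
  extensions <- vapply(
    split(kept$kin_type, kept$term),
    function(ext) paste(sort(unique(ext)), collapse = "|"),
    character(1)
  )
  length(unique(extensions))
}

#' Map the four-point binary feature space onto the core sibling types
#'
#' The two-feature structure's points are in bijection with the four
#' sibling kin types distinguished by referent sex and relative age
#' (speaker sex unspecified). Feature 1 is relative age (0 = elder,
#' 1 = younger), feature 2 is referent sex (0 = male, 1 = female), matching
#' the bit strings in `make_structure("binary_feature", 2)$space$points`.
#'
#' @return tibble with columns `index`, `bits`, `kin_code`, `referent_sex`,
#'   `relative_age`
#' @export
sibling_feature_map <- function() {
  struct <- make_structure("binary_feature", 2)
  pts <- struct$space$points
  decode <- function(bits) {
    age <- if (substr(bits, 2, 2) == "0") "e" else "y"
    sex <- if (substr(bits, 1, 1) == "0") "B" else "Z"
    paste0(age, sex)
  }
  codes <- vapply(pts$coord, decode, character(1))
  tibble::tibble(
    index = pts$index,
    bits = pts$coord,
    kin_code = codes,
    referent_sex = vapply(codes, function(cd)
      parse_kin_type(cd)$referent_sex, character(1)),
    relative_age = vapply(codes, function(cd)
      parse_kin_type(cd)$relative_age, character(1))
  )
}
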