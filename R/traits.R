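#' Default trait codebook
#'
#' Maps observed state names to binary codes for the three traits of the
#' motivating study: iris colour (dark = 0, bright = 1), nest type
#' (non-cavity = 0, cavity = 1) and coordinated parental care (uniparental =
#' 0, biparental or alloparental = 1). State names are canonicalized (case,
#' whitespace, hyphen/space/underscore) before lookup, and `?`, `NA` or empty
#' cells are treated as missing.
#'
#' @return A named list: trait name -> named 0/1 vector.
#' @export
default_codebook <- function() {
  list(
    iris = c(dark = 0, bright = 1),
    nest = c("non-cavity" = 0, cavity = 1),
    care = c(uniparental = 0, biparental = 1, alloparental = 1))
}

canonical_token <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ -]+", "_", x)
}

canonical_label <- function(x) canonical_token(x)

#' Load and encode a species-by-trait table
#'
#' Reads a delimited file (CSV or TSV, chosen by extension), codes every
#' trait column that appears in the codebook to 0/1, and validates the
#' result: unknown state tokens and duplicated species are errors that name
#' the offending rows.
#'
#' @param path Path to a delimited file with a header.
#' @param codebook Trait codebook, as [default_codebook()].
#' @param species_col Name of the species column.
#' @param missing_values Tokens treated as missing data.
#' @return A tibble with the species column plus one coded integer column
#'   (0/1/NA) per codebook trait found in the file; the codebook is attached
#'   as attribute `"codebook"`.
#' @export
load_trait_table <- function(path, codebook = default_codebook(),
                             species_col = "species",
                             missing_values = c("", "?", "NA")) {
  if (!file.exists(path)) abort(paste0("trait file not found: ", path))
  sep <- if (grepl("\\.tsv$|\\.txt$", tolower(path))) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!species_col %in% names(raw))
    abort(paste0("species column '", species_col, "' not found in ", path))
  species <- trimws(raw[[species_col]])
  dup <- unique(species[duplicated(species)])
  if (length(dup))
    abort(paste0("duplicated species: ", paste(head(dup, 5), collapse = ", ")))
  out <- code_trait_columns(raw, codebook, missing_values, species = species)
  attr(out, "codebook") <- codebook
  out
}

# Code every codebook trait column of `raw` to integer 0/1/NA; character
# columns are looked up after canonicalization, numeric 0/1 columns pass
# through validated.
code_trait_columns <- function(raw, codebook, missing_values = c("", "?", "NA"),
                               species = raw$species) {
  traits <- intersect(names(raw), names(codebook))
  if (!length(traits))
    abort("no trait column in the table matches the codebook")
  out <- tibble::tibble(species = species)
  for (tr in traits) {
    col <- raw[[tr]]
    if (is.numeric(col) || is.logical(col)) {
      col <- as.integer(col)
      if (any(!is.na(col) & !(col %in% c(0L, 1L))))
        abort(paste0("trait '", tr, "': numeric states must be 0/1/NA"))
      out[[tr]] <- col
      next
    }
    book <- codebook[[tr]]
    names(book) <- canonical_token(names(book))
    tok <- canonical_token(col)
    tok[tok %in% canonical_token(missing_values)] <- NA
    unknown <- which(!is.na(tok) & !(tok %in% names(book)))
    if (length(unknown))
      abort(paste0("trait '", tr, "': state '", col[unknown[1]],
                   "' in row ", unknown[1], " is not in the codebook (",
                   paste(names(book), collapse = ", "), ")"))
    out[[tr]] <- as.integer(book[tok])
  }
  out
}

#' Per-trait state counts
#'
#' @param table A coded trait table from [load_trait_table()] (or any tibble
#'   with a `species` column and 0/1/NA trait columns).
#' @return A tibble with one row per trait: counts of 0, 1 and missing.
#' @export
trait_summary <- function(table) {
  traits <- setdiff(names(table), "species")
  purrr::map_dfr(traits, function(tr) {
    x <- table[[tr]]
    tibble::tibble(trait = tr,
                   n0 = sum(x == 0, na.rm = TRUE),
                   n1 = sum(x == 1, na.rm = TRUE),
                   n_missing = sum(is.na(x)))
  })
}

#' Encode / decode a pair of binary traits as a 4-state character
#'
#' The combined state is `2 * trait1 + trait2`, i.e. `(0,0) -> 0`,
#' `(0,1) -> 1`, `(1,0) -> 2`, `(1,1) -> 3`.
#'
#' @param t1,t2 Vectors of 0/1 states (NA propagates).
#' @return `encode_pair`: integer vector in 0..3. `decode_pair`: a tibble
#'   with columns `trait1`, `trait2`.
#' @export
encode_pair <- function(t1, t2) {
  stopifnot(length(t1) == length(t2))
  ok <- function(x) all(is.na(x) | x %in% c(0, 1))
  if (!ok(t1) || !ok(t2)) abort("trait states must be 0, 1 or NA")
  as.integer(2L * t1 + t2)
}

#' @param state Integer vector of combined states in 0..3.
#' @rdname encode_pair
#' @export
decode_pair <- function(state) {
  if (any(!is.na(state) & !(state %in% 0:3)))
    abort("combined states must be in 0..3")
  tibble::tibble(trait1 = state %/% 2L, trait2 = state %% 2L)
}

#' Pair two traits and align them with a tree
#'
#' Complete-case pairing: species missing either trait are dropped, species
#' absent from the tree are dropped, and the tree is pruned to the species
#' with complete data. Labels are matched exactly after canonicalization
#' (case folding, space/underscore unification); no fuzzy matching.
#'
#' @param table A coded trait table ([load_trait_table()]).
#' @param trait1,trait2 Names of the two trait columns (trait 1 is the focal
#'   trait in the combined encoding).
#' @param tree A `phylo` object.
#' @param min_species Minimum usable species (default 4, the smallest sample
#'   that can inform a 4-state model).
#' @return A list: `states` (named 0..3 vector keyed by tree tip label),
#'   `tree` (pruned `phylo`), and `report` (tibble of dropped species with a
#'   `reason` of `"missing_trait"` or `"not_in_tree"`; tree tips without data
#'   appear as `"no_data_for_tip"`).
#' @export
pair_and_align <- function(table, trait1, trait2, tree, min_species = 4) {
  for (tr in c(trait1, trait2))
    if (!tr %in% names(table)) abort(paste0("trait column '", tr, "' not found"))
  tree <- validate_tree(tree)
  complete <- !is.na(table[[trait1]]) & !is.na(table[[trait2]])
  rep_missing <- tibble::tibble(species = table$species[!complete],
                                reason = "missing_trait")
  tab <- table[complete, ]
  key_tab <- canonical_label(tab$species)
  key_tip <- canonical_label(tree$tip.label)
  if (anyDuplicated(key_tab))
    abort("trait table species are not unique after canonicalization")
  if (anyDuplicated(key_tip))
    abort("tree tip labels are not unique after canonicalization")
  on_tree <- key_tab %in% key_tip
  rep_off <- tibble::tibble(species = tab$species[!on_tree],
                            reason = "not_in_tree")
  tab <- tab[on_tree, ]
  key_tab <- key_tab[on_tree]
  if (nrow(tab) < min_species)
    abort(paste0("only ", nrow(tab), " species have both traits and a tree tip; ",
                 "need at least ", min_species))
  keep_tips <- tree$tip.label[key_tip %in% key_tab]
  unkept <- setdiff(tree$tip.label, keep_tips)
  # tips already reported as missing_trait are not double-counted
  unkept <- unkept[!(canonical_label(unkept) %in% canonical_label(table$species))]
  rep_tip <- tibble::tibble(species = unkept, reason = "no_data_for_tip")
  pruned <- prune_to_taxa(tree, keep_tips)$tree
  idx <- match(canonical_label(pruned$tip.label), key_tab)
  states <- setNames(encode_pair(tab[[trait1]][idx], tab[[trait2]][idx]),
                     pruned$tip.label)
  list(states = states, tree = pruned,
       report = dplyr::bind_rows(rep_missing, rep_off, rep_tip))
}
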