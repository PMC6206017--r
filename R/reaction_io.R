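#' Reaction records and reaction sets
#'
#' A `reaction_record` holds one biochemical reaction: the metabolites on
#' each side and the reaction direction. A `reaction_set` is a taxon's
#' de-duplicated collection of records. Directions follow the usual arrow
#' conventions: `"LR"` (left to right), `"RL"` (right to left) and `"BOTH"`
#' (reversible).
#'
#' @param reaction_id Character scalar identifying the reaction.
#' @param substrates,products Character vectors of metabolite names; each
#'   side is treated as an ordered set (duplicates within a side are
#'   dropped, first occurrence kept).
#' @param direction One of `"LR"`, `"RL"`, `"BOTH"`.
#' @return `reaction_record()` returns an object of class
#'   `"reaction_record"`: a list with fields `reaction_id`, `substrates`,
#'   `products`, `direction`.
#' @examples
#' reaction_record("R1", c("ATP", "H2O"), c("ADP", "Pi"), "LR")
#' @export
reaction_record <- function(reaction_id, substrates, products,
                            direction = c("LR", "RL", "BOTH")) {
  direction <- match.arg(direction)
  substrates <- unique(as.character(substrates))
  products <- unique(as.character(products))
  if (length(substrates) == 0L || any(!nzchar(substrates)))
    stop_input("reaction ", reaction_id, ": substrates must be non-empty")
  if (length(products) == 0L || any(!nzchar(products)))
    stop_input("reaction ", reaction_id, ": products must be non-empty")
  structure(
    list(reaction_id = as.character(reaction_id),
         substrates = substrates, products = products,
         direction = direction),
    class = "reaction_record")
}

# Canonical content key: sides compared as sets, direction included.
record_key <- function(rec) {
  paste(paste(sort(rec$substrates), collapse = ";"),
        paste(sort(rec$products), collapse = ";"),
        rec$direction, sep = " | ")
}

#' @rdname reaction_record
#' @param taxon_id Character scalar naming the taxon.
#' @param records List of `reaction_record` objects; duplicates in
#'   (substrates, products, direction) are removed, first occurrence kept.
#' @return `reaction_set()` returns an object of class `"reaction_set"`
#'   with fields `taxon_id`, `records` and the reaction count `R`.
#' @export
reaction_set <- function(taxon_id, records) {
  if (!all(vapply(records, inherits, logical(1), "reaction_record")))
    stop_input("records must all be reaction_record objects")
  keys <- vapply(records, record_key, character(1))
  records <- records[!duplicated(keys)]
  structure(
    list(taxon_id = as.character(taxon_id), records = records,
         R = length(records)),
    class = "reaction_set")
}

#' @export
print.reaction_set <- function(x, ...) {
  cat("Reaction set for taxon '", x$taxon_id, "': ", x$R,
      " distinct reactions\n", sep = "")
  invisible(x)
}

#' Default metabolite synonym map
#'
#' Standardization map applied during name normalization. The built-in map
#' contains the single entry `NADP(H) -> NADPH`; extend it with
#' user-supplied entries (a named character vector, names are raw
#' spellings, values the standardized ones).
#'
#' @return Named character vector.
#' @export
default_synonyms <- function() {
  c("NADP(H)" = "NADPH")
}

#' Read a two-column synonym file
#'
#' @param path Path to a TSV with two columns: raw name, standardized name.
#'   Lines starting with `#` are ignored.
#' @return Named character vector merging the file entries over
#'   [default_synonyms()] (file entries win).
#' @export
read_synonyms <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 2L) stop_input("synonym file must have two columns")
  syn <- default_synonyms()
  syn[as.character(tab[[1]])] <- as.character(tab[[2]])
  syn
}

#' Normalize a metabolite name
#'
#' Strips a leading stoichiometric coefficient (an integer, a decimal,
#' a simple fraction, or the symbolic count `n`, followed by whitespace)
#' and then applies the synonym map. Comparison of normalized names is
#' exact and case-sensitive.
#'
#' @param raw Raw metabolite name.
#' @param synonyms Named character vector mapping raw spellings to
#'   standardized ones (applied after coefficient stripping).
#' @return Normalized name.
#' @examples
#' normalize_metabolite_name("2 ATP")       # "ATP"
#' normalize_metabolite_name("NADP(H)")     # "NADPH"
#' @export
normalize_metabolite_name <- function(raw, synonyms = default_synonyms()) {
  x <- trimws(raw)
  if (!nzchar(x)) stop_input("empty metabolite name")
  x <- sub("^(n|[0-9]+(\\.[0-9]+)?(/[0-9]+)?)[[:space:]]+", "", x)
  if (!nzchar(x))
    stop_input("metabolite name '", raw, "' empty after coefficient removal")
  hit <- match(x, names(synonyms))
  if (!is.na(hit)) x <- unname(synonyms[hit])
  x
}

arrow_table <- list(
  LR = c("=>", "⇒", "→", "->"),
  RL = c("<=", "⇐", "←"),
  BOTH = c("<=>", "⇔", "<->")
)

#' Parse a free-text reaction equation
#'
#' The equation must contain exactly one reaction arrow. Accepted arrows:
#' `=>`/`⇒`/`→` (left to right), `<=`/`⇐` (right to left) and
#' `<=>`/`⇔` (reversible). Each side is a `+`-separated metabolite list.
#' For right-to-left arrows the sides are stored unswapped with direction
#' `"RL"`.
#'
#' @param equation Character scalar, e.g. `"A + B => C"`.
#' @param reaction_id Identifier to attach to the record.
#' @param synonyms Synonym map passed to [normalize_metabolite_name()].
#' @return A [reaction_record()].
#' @export
equation_to_record <- function(equation, reaction_id = "R1",
                               synonyms = default_synonyms()) {
  eq <- trimws(equation)
  # longest arrows first so "<=>" is not read as "<=" + ">"
  arrows <- c(BOTH = "<=>", BOTH = "⇔", BOTH = "<->",
              LR = "=>", LR = "⇒", LR = "→", LR = "->",
              RL = "<=", RL = "⇐", RL = "←")
  found <- NULL
  for (i in seq_along(arrows)) {
    if (grepl(arrows[i], eq, fixed = TRUE)) {
      found <- i
      break
    }
  }
  if (is.null(found)) stop_input("no reaction arrow in: ", equation)
  tok <- arrows[found]
  parts <- strsplit(eq, tok, fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop_input("malformed equation (need exactly one arrow): ", equation)
  # reject a second, different arrow on either side
  rest <- arrows[-found]
  for (p in parts) for (a in rest)
    if (grepl(a, p, fixed = TRUE))
      stop_input("multiple reaction arrows in: ", equation)
  split_side <- function(s) {
    xs <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    xs <- xs[nzchar(xs)]
    if (length(xs) == 0L) stop_input("empty reaction side in: ", equation)
    vapply(xs, normalize_metabolite_name, character(1), synonyms = synonyms,
           USE.NAMES = FALSE)
  }
  reaction_record(reaction_id, split_side(parts[1]), split_side(parts[2]),
                  names(arrows)[found])
}

#' Parse a per-species reaction file
#'
#' Reads a reaction dataset in one of two dialects and applies the
#' preprocessing pipeline in a fixed order: (i) transcode to UTF-8,
#' (ii) drop byte-identical duplicated lines, (iii) standardize names via
#' the synonym map, (iv) strip stoichiometric coefficients. Records that
#' become identical in (substrates, products, direction) after
#' normalization are also collapsed.
#'
#' Canonical TSV dialect: four tab-separated columns
#' `reaction_id  substrates  products  direction`, sides `;`-separated,
#' direction one of `LR`, `RL`, `BOTH`. Equation dialect: one equation per
#' line, `#` comments allowed.
#'
#' @param path Path to the reaction file.
#' @param dialect `"tsv"` or `"equation"`.
#' @param taxon_id Taxon identifier; defaults to the file base name.
#' @param synonyms Synonym map (named character vector).
#' @param encoding Source encoding, transcoded to UTF-8 on read.
#' @return A [reaction_set()].
#' @export
parse_reaction_file <- function(path, dialect = c("tsv", "equation"),
                                taxon_id = NULL,
                                synonyms = default_synonyms(),
                                encoding = "UTF-8") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("cannot read reaction file: ", path)
  taxon_id <- taxon_id %||% tools::file_path_sans_ext(basename(path))
  con <- file(path, encoding = encoding)
  on.exit(close(con), add = TRUE)
  lines <- enc2utf8(readLines(con, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop_input("empty reaction file: ", path)
  lines <- lines[!duplicated(lines)]   # step (ii): duplicated formulas

  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    rec <- tryCatch(
      if (dialect == "tsv") parse_tsv_line(ln, synonyms)
      else equation_to_record(ln, reaction_id = paste0("R", i),
                              synonyms = synonyms),
      error = function(e)
        stop_input("parse error at line ", i, " of ", path, ": ",
                   conditionMessage(e)))
    recs[[i]] <- rec
  }
  reaction_set(taxon_id, recs)
}

parse_tsv_line <- function(line, synonyms) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 4L)
    stop_input("expected 4 tab-separated fields, got ", length(f))
  if (!f[4] %in% c("LR", "RL", "BOTH"))
    stop_input("unknown direction '", f[4], "'")
  side <- function(s) {
    xs <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    xs <- xs[nzchar(xs)]
    if (length(xs) == 0L) stop_input("empty reaction side")
    vapply(xs, normalize_metabolite_name, character(1), synonyms = synonyms,
           USE.NAMES = FALSE)
  }
  reaction_record(f[1], side(f[2]), side(f[3]), f[4])
}

#' Write a reaction set in the canonical TSV dialect
#'
#' Round-trips with [parse_reaction_file()]: parsing the written file
#' yields an identical `reaction_set`.
#'
#' @param rs A [reaction_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_file <- function(rs, path) {
  stopifnot(inherits(rs, "reaction_set"))
  lines <- vapply(rs$records, function(r)
    paste(r$reaction_id, paste(r$substrates, collapse = ";"),
          paste(r$products, collapse = ";"), r$direction, sep = "\t"),
    character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}
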