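# Cross-species protease gene mapping (human, chimpanzee, mouse, rat).
#
# The packaged table is a small synthetic stand-in covering well-known
# protease families (see inst/extdata/orthologs_synthetic.csv); users
# studying other genes should supply their own full ortholog table with the
# same four columns. An empty cell means "no ortholog in that species".

paa_species <- c("human", "chimpanzee", "mouse", "rat")

#' Load an ortholog table
#'
#' @param path Optional CSV with columns `human`, `chimpanzee`, `mouse`,
#'   `rat`; when `NULL` the small packaged synthetic table is used.
#' @return Data frame with the four species columns; empty cells are `NA`.
#' @export
load_ortholog_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "orthologs_synthetic.csv",
                                package = "proteasekit")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(paa_species, colnames(df))
  if (length(missing) > 0) {
    stop("ortholog table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[paa_species]
}

#' Map a protease gene symbol between species
#'
#' Looks a gene up (case-insensitively) in the `from` species column and
#' returns the ortholog symbol in the `to` species. A gene that is present
#' in the table but has no ortholog in the target species returns `NA` with
#' a warning (an explicit "no ortholog" signal); a gene absent from the
#' table raises a not-found error, so the two situations are never
#' conflated. Mapping a species to itself returns the recorded symbol.
#'
#' @param gene Gene symbol (e.g. `"MMP9"`).
#' @param from,to One of `"human"`, `"chimpanzee"`, `"mouse"`, `"rat"`.
#' @param table Optional ortholog table from [load_ortholog_table()]; the
#'   packaged table is used when omitted.
#' @return The ortholog symbol, or `NA_character_` when the gene has no
#'   ortholog in `to`.
#' @export
species_to_species <- function(gene, from, to, table = NULL) {
  from <- match.arg(from, paa_species)
  to <- match.arg(to, paa_species)
  if (is.null(table)) table <- load_ortholog_table()
  idx <- match(label_key(gene), label_key(table[[from]]))
  if (is.na(idx)) {
    stop_not_found(paste0("gene '", gene, "' not found in the ", from,
                          " column of the ortholog table"))
  }
  val <- table[[to]][idx]
  if (is.na(val) || trim_label(val) == "") {
    warning("gene '", gene, "' has no ", to, " ortholog", call. = FALSE)
    return(NA_character_)
  }
  trim_label(val)
}
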