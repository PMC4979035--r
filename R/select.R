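#' Select atoms with a small expression language
#'
#' Grammar (case-insensitive keywords, left-to-right, `and` binds tighter
#' than `or`):
#' \preformatted{
#'   expr    := term { "or" term }
#'   term    := factor { "and" factor }
#'   factor  := "not" factor | "(" expr ")" | primary
#'   primary := "all" | "none" | "protein" | "ligand" | "backbone" | "calpha"
#'            | "segment" <protein|ligand|other>
#'            | "name" <tok>...      (atom-name list)
#'            | "resname" <tok>...   (residue-name list)
#'            | "resid" <n | a:b | a "to" b> [,...]
#' }
#' `backbone` means atoms named N, CA, C, O in the protein segment; `calpha`
#' means protein CA atoms. The result records the expression as provenance
#' and is deterministic; an empty selection is allowed.
#'
#' @param topology a [Topology-class]
#' @param expr selection expression string
#' @return an [AtomSelection-class]
#' @examples
#' \dontrun{atomSelect(topo, "resid 214 and name O")}
#' @export
atomSelect <- function(topology, expr) {
  a <- topology@atoms
  toks <- regmatches(expr, gregexpr("\\(|\\)|[^()\\s]+", expr, perl = TRUE))[[1]]
  if (!length(toks)) stop("empty selection expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) tolower(toks[pos]) else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  kw <- c("and", "or", "not", "(", ")", "all", "none", "protein", "ligand",
          "backbone", "calpha", "segment", "name", "resname", "resid", "to")

  parsePrimary <- function() {
    t <- peek()
    if (is.na(t)) stop("selection parse error: unexpected end of '", expr, "'")
    if (t == "(") {
      advance(); v <- parseOr()
      if (!identical(peek(), ")")) stop("selection parse error: missing ')' in '", expr, "'")
      advance(); return(v)
    }
    if (t == "not") { advance(); return(!parsePrimary()) }
    advance()
    switch(t,
      all      = rep(TRUE, nrow(a)),
      none     = rep(FALSE, nrow(a)),
      protein  = a$segment == "protein",
      ligand   = a$segment == "ligand",
      backbone = a$segment == "protein" & a$name %in% c("N", "CA", "C", "O"),
      calpha   = a$segment == "protein" & a$name == "CA",
      segment  = {
        val <- tolower(advance())
        if (!val %in% .segmentLevels)
          stop("selection parse error: unknown segment '", val, "'")
        a$segment == val
      },
      name     = a$name %in% toupper(.takeList(kw, peek, advance)),
      resname  = a$resname %in% toupper(.takeList(kw, peek, advance)),
      resid    = a$resid %in% .takeResids(kw, peek, advance, expr),
      stop("selection parse error: unexpected token '", t, "' in '", expr, "'")
    )
  }
  parseAnd <- function() {
    v <- parsePrimary()
    while (identical(peek(), "and")) { advance(); v <- v & parsePrimary() }
    v
  }
  parseOr <- function() {
    v <- parseAnd()
    while (identical(peek(), "or")) { advance(); v <- v | parseAnd() }
    v
  }
  mask <- parseOr()
  if (pos <= length(toks))
    stop("selection parse error: trailing token '", toks[pos], "' in '", expr, "'")
  new("AtomSelection", indices = which(mask), expr = expr)
}

.takeList <- function(kw, peek, advance) {
  out <- character()
  while (!is.na(peek()) && !peek() %in% kw) out <- c(out, advance())
  if (!length(out)) stop("selection parse error: empty name list")
  out
}

.takeResids <- function(kw, peek, advance, expr) {
  out <- integer()
  repeat {
    t <- peek()
    if (is.na(t) || (t %in% kw && t != "to")) break
    tok <- advance()
    if (grepl("^-?[0-9]+:-?[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, ":")[[1]])
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^-?[0-9]+$", tok)) {
      lo <- as.integer(tok)
      if (identical(peek(), "to")) {
        advance()
        hi <- suppressWarnings(as.integer(advance()))
        if (is.na(hi)) stop("selection parse error: bad range in '", expr, "'")
        out <- c(out, lo:hi)
      } else out <- c(out, lo)
    } else stop("selection parse error: bad resid token '", tok, "' in '", expr, "'")
  }
  if (!length(out)) stop("selection parse error: empty resid list")
  out
}
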