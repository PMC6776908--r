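# Selection expression grammar (case-insensitive keywords):
#   expr    := orExpr
#   orExpr  := andExpr ('or' andExpr)*
#   andExpr := unary ('and' unary)*
#   unary   := 'not' unary | '(' expr ')' | term
#   term    := 'chain' <id> | 'resid' <a>[-<b>] | 'name' <n1,n2,...>
#            | 'backbone' | 'calpha' | 'heavy'
# backbone = atoms named N, CA, C, O; calpha = CA; heavy = element != H.

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

.tokenizeSelection <- function(expression) {
  txt <- gsub("([()])", " \\1 ", expression)
  tokens <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  tokens[nzchar(tokens)]
}

.parseSelection <- function(tokens, atoms) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(tok) {
    stop(sprintf("selection syntax error at token '%s'", tok), call. = FALSE)
  }

  parseOr <- function() {
    m <- parseAnd()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      m <- m | parseAnd()
    }
    m
  }
  parseAnd <- function() {
    m <- parseUnary()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      m <- m & parseUnary()
    }
    m
  }
  parseUnary <- function() {
    tok <- peek()
    if (is.na(tok)) fail("<end of expression>")
    low <- tolower(tok)
    if (low == "not") { advance(); return(!parseUnary()) }
    if (tok == "(") {
      advance()
      m <- parseOr()
      if (is.na(peek()) || peek() != ")") fail(ifelse(is.na(peek()),
                                                     "<end of expression>",
                                                     peek()))
      advance()
      return(m)
    }
    parseTerm()
  }
  parseTerm <- function() {
    tok <- advance()
    switch(tolower(tok),
      chain = {
        arg <- advance()
        if (is.na(arg)) fail("<missing chain id>")
        atoms$chain == arg
      },
      resid = {
        arg <- advance()
        if (is.na(arg) || !grepl("^-?[0-9]+(--?[0-9]+)?$", arg)) fail(arg)
        if (grepl("^-?[0-9]+$", arg)) {
          atoms$resid == as.integer(arg)
        } else {
          ab <- regmatches(arg, regexec("^(-?[0-9]+)-(-?[0-9]+)$", arg))[[1]]
          atoms$resid >= as.integer(ab[2]) & atoms$resid <= as.integer(ab[3])
        }
      },
      name = {
        arg <- advance()
        if (is.na(arg)) fail("<missing atom names>")
        atoms$name %in% strsplit(arg, ",")[[1]]
      },
      backbone = atoms$name %in% .BACKBONE_NAMES,
      calpha = atoms$name == "CA",
      heavy = atoms$element != "H",
      fail(tok))
  }

  mask <- parseOr()
  if (!is.na(peek())) fail(peek())
  mask
}

#' Resolve an atom selection expression on a Structure
#'
#' The mini-language combines terms \code{chain <id>}, \code{resid <a>-<b>},
#' \code{resid <a>}, \code{name <n1,n2,...>}, \code{backbone} (N, CA, C, O),
#' \code{calpha} (CA) and \code{heavy} (element other than H) with
#' \code{and}, \code{or}, \code{not} and parentheses. Resolution is
#' deterministic and returns indices in structure order; an empty result is
#' legal.
#'
#' @param structure a \linkS4class{Structure}.
#' @param expression selection expression text.
#' @return a \linkS4class{Selection}
#' @examples
#' h <- makeIdealHelix(10)
#' selectAtoms(h, "calpha")
#' selectAtoms(h, "resid 2-5 and backbone")
#' @export
selectAtoms <- function(structure, expression) {
  stopifnot(is(structure, "Structure"))
  tokens <- .tokenizeSelection(expression)
  if (length(tokens) == 0)
    stop("empty selection expression", call. = FALSE)
  mask <- .parseSelection(tokens, structure@atoms)
  new("Selection", expression = expression, indices = which(mask))
}

# Accept a Selection, an expression string, integer indices, or NULL
# (= all atoms) wherever an atom subset is needed.
.asIndices <- function(structure, sel) {
  if (is.null(sel)) return(seq_len(nAtoms(structure)))
  if (is(sel, "Selection")) return(sel@indices)
  if (is.character(sel)) return(selectAtoms(structure, sel)@indices)
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    stopifnot(all(idx >= 1), all(idx <= nAtoms(structure)))
    return(idx)
  }
  stop("cannot interpret selection of class ", class(sel)[1], call. = FALSE)
}
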