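# Atom selection mini-language.
#
# Grammar (case-insensitive keywords):
#   expr      := term (("and" | "or") term)*   -- left-associative
#   term      := "not" term | "(" expr ")" | primitive
#   primitive := "resid" range+ | "resname" TOKEN+ | "name" TOKEN+ |
#                "chain" TOKEN+ | "role" TOKEN+ | "element" TOKEN+ |
#                "protein" | "lipid" | "heme" | "solvent" |
#                "heavy" | "hydrogen" | "backbone" | "calpha" | "all"
#   range     := INT | INT "-" INT | INT ":" INT
# "and" binds tighter than "or".

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

.sel_tokenize <- function(expression) {
  expression <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.sel_is_value <- function(tok) {
  !(tolower(tok) %in% c("and", "or", "not", "(", ")", "resid", "resname",
                        "name", "chain", "role", "element", "protein",
                        "lipid", "heme", "solvent", "heavy", "hydrogen",
                        "backbone", "calpha", "all"))
}

# recursive-descent parser producing a logical mask over atoms
.sel_parse <- function(toks, atoms) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  fail <- function(msg) stop("selection syntax error: ", msg,
                             " (near token ", pos, ")", call. = FALSE)

  parse_range_vals <- function() {
    vals <- character(0)
    while (!is.na(peek()) && .sel_is_value(peek())) vals <- c(vals, advance())
    if (!length(vals)) fail("expected at least one value")
    vals
  }
  prim_resid <- function() {
    vals <- parse_range_vals()
    keep <- rep(FALSE, nrow(atoms))
    for (v in vals) {
      if (grepl("^-?[0-9]+[-:][0-9]+$", v)) {
        ab <- as.integer(strsplit(v, "[-:]")[[1]])
        keep <- keep | (atoms$residue_seq >= ab[1] &
                        atoms$residue_seq <= ab[2])
      } else if (grepl("^-?[0-9]+$", v)) {
        keep <- keep | atoms$residue_seq == as.integer(v)
      } else fail(paste0("bad residue range '", v, "'"))
    }
    keep
  }
  prim_match <- function(col) {
    vals <- toupper(parse_range_vals())
    toupper(atoms[[col]]) %in% vals
  }
  primitive <- function() {
    tok <- tolower(peek())
    if (is.na(tok)) fail("unexpected end of expression")
    switch(tok,
      "resid" = { advance(); prim_resid() },
      "resname" = { advance(); prim_match("residue_name") },
      "name" = { advance(); prim_match("atom_name") },
      "chain" = { advance(); prim_match("chain") },
      "role" = { advance(); prim_match("role") },
      "element" = { advance(); prim_match("element") },
      "protein" = { advance(); atoms$role == "protein" },
      "lipid" = { advance(); atoms$role == "lipid" },
      "heme" = { advance(); atoms$role == "heme" },
      "solvent" = { advance(); atoms$role == "solvent" },
      "heavy" = { advance(); atoms$element != "H" },
      "hydrogen" = { advance(); atoms$element == "H" },
      "backbone" = { advance();
        atoms$role == "protein" &
          toupper(atoms$atom_name) %in% .BACKBONE_NAMES },
      "calpha" = { advance();
        atoms$role == "protein" & toupper(atoms$atom_name) == "CA" },
      "all" = { advance(); rep(TRUE, nrow(atoms)) },
      fail(paste0("unknown keyword '", peek(), "'")))
  }
  term <- function() {
    tok <- tolower(peek())
    if (is.na(tok)) fail("unexpected end of expression")
    if (tok == "not") { advance(); return(!term()) }
    if (tok == "(") {
      advance()
      m <- expr()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(m)
    }
    primitive()
  }
  and_expr <- function() {
    m <- term()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      m <- m & term()
    }
    m
  }
  expr <- function() {
    m <- and_expr()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      m <- m | and_expr()
    }
    m
  }
  m <- expr()
  if (!is.na(peek())) fail(paste0("trailing token '", peek(), "'"))
  m
}

#' Select atoms by expression
#'
#' Deterministic atom selection supporting residue ranges
#' (`"resid 285-289"`), atom-name lists (`"name CA CB"`), residue names,
#' chains, role filters (`"protein"`, `"lipid"`, `"heme"`, `"solvent"`),
#' `"heavy"`, `"hydrogen"`, `"backbone"`, `"calpha"`, combined with
#' `and` / `or` / `not` and parentheses. An empty selection is legal.
#'
#' @param model structure_model.
#' @param expression selection expression (see Details).
#' @return object of class `atom_selection`: list with `indices`
#'   (atom_ids, in model order), `rows` (row indices into `model$atoms`)
#'   and `expression`.
#' @examples
#' bl <- build_toy_bilayer(2, 2)
#' select_atoms(bl, "name H1 and lipid")
#' @export
select_atoms <- function(model, expression) {
  toks <- .sel_tokenize(expression)
  if (!length(toks)) stop("selection syntax error: empty expression")
  mask <- .sel_parse(toks, model$atoms)
  structure(list(indices = model$atoms$atom_id[mask],
                 rows = which(mask),
                 expression = expression),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection: ", length(x$indices), " atoms  [",
      x$expression, "]\n", sep = "")
  invisible(x)
}

# internal: row indices for an expression (or pass-through integer rows)
.sel_rows <- function(model, sel) {
  if (is.character(sel)) select_atoms(model, sel)$rows
  else if (inherits(sel, "atom_selection")) sel$rows
  else as.integer(sel)
}
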