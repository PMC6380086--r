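#' Symbolic terms
#'
#' Terms are the universal currency of the virtual machine: stimuli, thread
#' identities, messages and memory contents are all functor/argument trees
#' with logic variables at the leaves.  An atom is a term with zero
#' arguments; a list such as `[green]` is sugar for a term with the reserved
#' functor `"[]"` holding its elements.
#'
#' @param functor character scalar, the functor (or atom) name.
#' @param args list of `vm_term`/`vm_var` arguments (possibly empty).
#' @return A `vm_term` object.
#' @examples
#' vm_term("motor", list(vm_var("X")))
#' term("sensor(left([green]),right([red]),sample([red]))")
#' @export
vm_term <- function(functor, args = list()) {
  stopifnot(is.character(functor), length(functor) == 1L, nzchar(functor))
  structure(list(functor = functor, args = args), class = "vm_term")
}

#' Logic variables
#'
#' Variables are distinct leaf objects identified by name; in the canonical
#' syntax any identifier starting with an upper-case letter or underscore is
#' read as a variable.
#'
#' @param name character scalar variable name.
#' @return A `vm_var` object.
#' @export
vm_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name), class = "vm_var")
}

## structural checks on the list fields, not class dispatch: these run in
## the interpreter's innermost loops
is_term <- function(x) is.list(x) && !is.null(x[["functor"]])
is_var <- function(x) is.list(x) && !is.null(x[["name"]])
is_atom <- function(x) is_term(x) && length(x[["args"]]) == 0L

#' @export
print.vm_term <- function(x, ...) {
  cat(term_format(x), "\n")
  invisible(x)
}

#' @export
print.vm_var <- function(x, ...) {
  cat(term_format(x), "\n")
  invisible(x)
}

#' Render a term in canonical syntax
#'
#' Canonical syntax mirrors the trace notation: `functor(arg1,arg2,...)`,
#' lists in square brackets, variables upper-case.
#'
#' @param x a `vm_term` or `vm_var`.
#' @return character scalar.
#' @export
term_format <- function(x) {
  if (is_var(x)) return(x$name)
  if (!is_term(x)) stop("term_format: not a term: ", class(x)[1L])
  if (x$functor == "[]") {
    return(paste0("[", paste(vapply(x$args, term_format, ""), collapse = ","), "]"))
  }
  if (length(x$args) == 0L) return(x$functor)
  paste0(x$functor, "(", paste(vapply(x$args, term_format, ""), collapse = ","), ")")
}

## --- canonical-syntax parser (recursive descent over a token stream) -----

term_tokenize <- function(s) {
  ## '#' appears only in machine-renamed variable names (e.g. "X#12")
  pat <- "[A-Za-z_][A-Za-z0-9_#]*|[0-9]+|[(),\\[\\]]"
  m <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) stop("term parse error: no tokens in ", sQuote(s))
  toks <- regmatches(s, gregexpr(pat, s, perl = TRUE))[[1L]]
  residue <- gsub(pat, "", gsub("[[:space:]]", "", s), perl = TRUE)
  if (nzchar(residue)) {
    stop("term parse error: unexpected character(s) ", sQuote(residue), " in ", sQuote(s))
  }
  toks
}

#' Parse canonical term syntax
#'
#' @param s character scalar, e.g. `"sensor(left([green]),right([red]),sample([red]))"`.
#' @return A `vm_term` or `vm_var`.
#' @export
term <- function(s) {
  if (!is.character(s)) {
    if (is_term(s) || is_var(s)) return(s)
    stop("term: expected a term, variable or canonical string")
  }
  toks <- term_tokenize(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  expect <- function(t) {
    got <- advance()
    if (is.na(got) || got != t) {
      stop("term parse error in ", sQuote(s), ": expected ", sQuote(t),
           ", got ", sQuote(if (is.na(got)) "<end>" else got))
    }
    got
  }
  parse_args <- function(close) {
    args <- list()
    if (!is.na(peek()) && peek() == close) return(args)
    repeat {
      args[[length(args) + 1L]] <- parse_term()
      if (is.na(peek())) stop("term parse error in ", sQuote(s), ": unclosed ", close)
      if (peek() == ",") {
        advance()
      } else {
        break
      }
    }
    args
  }
  parse_term <- function() {
    tok <- advance()
    if (is.na(tok)) stop("term parse error in ", sQuote(s), ": unexpected end")
    if (tok == "[") {
      args <- parse_args("]")
      expect("]")
      return(vm_term("[]", args))
    }
    if (grepl("^[A-Z_]", tok)) return(vm_var(tok))
    if (!grepl("^[a-z0-9]", tok)) {
      stop("term parse error in ", sQuote(s), ": unexpected token ", sQuote(tok))
    }
    if (!is.na(peek()) && peek() == "(") {
      advance()
      args <- parse_args(")")
      expect(")")
      return(vm_term(tok, args))
    }
    vm_term(tok)
  }
  out <- parse_term()
  if (!is.na(peek())) {
    stop("term parse error in ", sQuote(s), ": trailing token ", sQuote(peek()))
  }
  out
}

## --- substitutions --------------------------------------------------------

empty_subst <- function() list()

#' Apply a substitution to a term
#'
#' Substitutions are idempotent maps from variable names to terms; applying
#' twice equals applying once.
#'
#' @param x term or variable.
#' @param s substitution (named list from [unify()]).
#' @return the instantiated term.
#' @export
apply_subst <- function(x, s) {
  if (length(s) == 0L) return(x)
  walk <- function(t) {
    nm <- t[["name"]]
    if (!is.null(nm)) {
      b <- s[[nm]]
      if (is.null(b)) t else walk(b)
    } else {
      if (length(t[["args"]])) t[["args"]] <- lapply(t[["args"]], walk)
      t
    }
  }
  walk(x)
}

occurs_in <- function(v, t, s) {
  nm <- t[["name"]]
  if (!is.null(nm)) {
    if (nm == v) return(TRUE)
    b <- s[[nm]]
    return(!is.null(b) && occurs_in(v, b, s))
  }
  for (a in t[["args"]]) if (occurs_in(v, a, s)) return(TRUE)
  FALSE
}

subst_walk <- function(t, s) {
  repeat {
    nm <- t[["name"]]
    if (is.null(nm)) return(t)
    b <- s[[nm]]
    if (is.null(b)) return(t)
    t <- b
  }
}

#' Unify two terms
#'
#' Computes the most general unifier of `a` and `b` (occurs-check enabled),
#' or returns `NULL` on clash.  On success, applying the result to both
#' inputs yields identical terms.
#'
#' @param a,b terms (or canonical strings, which are parsed).
#' @param s an existing substitution to extend.
#' @return A substitution (named list of variable bindings) or `NULL`.
#' @examples
#' unify(term("motor(X)"), term("motor(cs)"))
#' @export
unify <- function(a, b, s = empty_subst()) {
  if (is.character(a)) a <- term(a)
  if (is.character(b)) b <- term(b)
  a <- subst_walk(a, s)
  b <- subst_walk(b, s)
  an <- a[["name"]]
  bn <- b[["name"]]
  if (!is.null(an)) {
    if (!is.null(bn) && an == bn) return(s)
    if (occurs_in(an, b, s)) return(NULL)
    s[[an]] <- b
    return(s)
  }
  if (!is.null(bn)) {
    if (occurs_in(bn, a, s)) return(NULL)
    s[[bn]] <- a
    return(s)
  }
  aa <- a[["args"]]
  ba <- b[["args"]]
  if (a[["functor"]] != b[["functor"]] || length(aa) != length(ba)) return(NULL)
  for (i in seq_along(aa)) {
    s <- unify(aa[[i]], ba[[i]], s)
    if (is.null(s)) return(NULL)
  }
  s
}

#' Structural term equality
#'
#' @param a,b terms.
#' @return logical scalar.
#' @export
term_equal <- function(a, b) {
  identical(term_format(term(a)), term_format(term(b)))
}

## Rename every variable in a term with a fresh suffix (standardizing apart
## before each deduction so distinct threads never share variable objects).
term_rename <- function(x, suffix) {
  walk <- function(t) {
    nm <- t[["name"]]
    if (!is.null(nm)) {
      t[["name"]] <- paste0(sub("#.*$", "", nm), "#", suffix)
      return(t)
    }
    if (length(t[["args"]])) t[["args"]] <- lapply(t[["args"]], walk)
    t
  }
  walk(x)
}

term_vars <- function(x) {
  acc <- character()
  walk <- function(t) {
    if (is_var(t)) {
      acc[[length(acc) + 1L]] <<- t$name
    } else {
      for (a in t$args) walk(a)
    }
  }
  walk(x)
  unique(acc)
}

term_is_ground <- function(x) length(term_vars(x)) == 0L
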