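# Minimal Turtle reader for OWL class hierarchies.
#
# No installed R package parses Turtle, so this module implements the subset
# that OWL class-hierarchy documents actually use: @prefix/@base (and the
# SPARQL-style PREFIX/BASE forms), IRIs, prefixed names, `a`, the `;` and `,`
# continuations, plain/language-tagged/typed literals including long """..."""
# strings, booleans, comments, and blank-node property lists `[...]` (skipped
# as anonymous nodes).  Collections `(...)` are skipped likewise.  Triples are
# emitted in source order, which downstream code relies on for the
# first-listed-superclass rule.

ttl_tokenize <- function(text) {
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- vector("list", 0L)
  i <- 1L
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    c0 <- chars[i]
    if (c0 %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }
    if (c0 == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (c0 == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("Turtle format error: unterminated IRI at char ", i)
      push("iri", paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
      next
    }
    if (c0 == '"' || c0 == "'") {
      q <- c0
      long <- i + 2L <= n && chars[i + 1L] == q && chars[i + 2L] == q
      if (long) {
        j <- i + 3L
        repeat {
          if (j + 2L > n) stop("Turtle format error: unterminated long string at char ", i)
          if (chars[j] == q && chars[j + 1L] == q && chars[j + 2L] == q) break
          if (chars[j] == "\\") j <- j + 1L
          j <- j + 1L
        }
        raw_str <- if (j > i + 3L) paste0(chars[(i + 3L):(j - 1L)], collapse = "") else ""
        i <- j + 3L
      } else {
        j <- i + 1L
        repeat {
          if (j > n) stop("Turtle format error: unterminated string at char ", i)
          if (chars[j] == q) break
          if (chars[j] == "\\") j <- j + 1L
          j <- j + 1L
        }
        raw_str <- if (j > i + 1L) paste0(chars[(i + 1L):(j - 1L)], collapse = "") else ""
        i <- j + 1L
      }
      push("literal", ttl_unescape(raw_str))
      # optional @lang or ^^datatype
      if (i <= n && chars[i] == "@") {
        j <- i + 1L
        while (j <= n && grepl("[A-Za-z0-9-]", chars[j])) j <- j + 1L
        push("lang", paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
        i <- j
      } else if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        push("dtype_marker", "^^")
        i <- i + 2L
      }
      next
    }
    if (c0 %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(c0, c0)
      i <- i + 1L
      next
    }
    # bare token: prefixed name, directive, boolean, number, 'a'
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\r", "\n", ";", ",", "[", "]", "(", ")", '"', "'", "<", "#") &&
           !(chars[j] == "." && (j == n || chars[j + 1L] %in% c(" ", "\t", "\r", "\n") || j == n))) {
      j <- j + 1L
    }
    # trailing '.' directly attached to a name ends the statement
    tok <- paste0(chars[i:(j - 1L)], collapse = "")
    if (!nzchar(tok)) { # lone '.'
      push(".", ".")
      i <- i + 1L
      next
    }
    push("name", tok)
    i <- j
  }
  toks
}

ttl_unescape <- function(s) {
  if (!grepl("\\", s, fixed = TRUE)) return(s)
  s <- gsub("\\\\n", "\n", s)
  s <- gsub("\\\\t", "\t", s)
  s <- gsub("\\\\r", "\r", s)
  s <- gsub('\\\\"', '"', s)
  s <- gsub("\\\\'", "'", s)
  gsub("\\\\\\\\", "\\\\", s)
}

# Parse Turtle text into an ordered triple table (subject, predicate, object,
# object_kind in {iri, literal, blank}).
ttl_triples <- function(text, source = "<text>") {
  toks <- ttl_tokenize(text)
  prefixes <- list()
  base <- ""
  trip_s <- character(); trip_p <- character(); trip_o <- character(); trip_k <- character()
  k <- 1L
  ntok <- length(toks)

  peek <- function() if (k <= ntok) toks[[k]] else NULL
  advance <- function() k <<- k + 1L
  fail <- function(msg) stop("Turtle format error in '", source, "' near token ", k, ": ", msg)

  resolve_name <- function(value) {
    if (value == "a") return(IRI_RDF_TYPE)
    if (grepl("^_:", value)) return(list(kind = "blank", iri = value))
    m <- regmatches(value, regexec("^([A-Za-z0-9._-]*):(.*)$", value))[[1]]
    if (length(m) == 3) {
      pfx <- m[2]
      if (!is.null(prefixes[[paste0("p_", pfx)]])) {
        return(paste0(prefixes[[paste0("p_", pfx)]], m[3]))
      }
      fail(paste0("undeclared prefix '", pfx, ":'"))
    }
    value # bare token (boolean/number) treated as literal downstream
  }

  skip_bracketed <- function(open, close) {
    depth <- 1L
    while (depth > 0L) {
      t <- peek()
      if (is.null(t)) fail(paste0("unbalanced '", open, "'"))
      if (t$type == open) depth <- depth + 1L
      if (t$type == close) depth <- depth - 1L
      advance()
    }
  }

  # returns list(kind, value) consuming one RDF term (plus lang/dtype)
  read_term <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of input")
    if (t$type == "iri") {
      advance()
      v <- t$value
      if (!grepl("^[a-zA-Z][a-zA-Z0-9+.-]*:", v)) v <- paste0(base, v)
      return(list(kind = "iri", value = v))
    }
    if (t$type == "literal") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "lang") {
        advance()
        return(list(kind = "literal", value = t$value, lang = nxt$value))
      }
      if (!is.null(nxt) && nxt$type == "dtype_marker") {
        advance()
        dt <- peek()
        if (is.null(dt)) fail("dangling '^^'")
        advance()
        return(list(kind = "literal", value = t$value, lang = NA_character_))
      }
      return(list(kind = "literal", value = t$value, lang = NA_character_))
    }
    if (t$type == "[") {
      advance()
      skip_bracketed("[", "]")
      return(list(kind = "blank", value = paste0("_:anon", k)))
    }
    if (t$type == "(") {
      advance()
      skip_bracketed("(", ")")
      return(list(kind = "blank", value = paste0("_:list", k)))
    }
    if (t$type == "name") {
      advance()
      r <- resolve_name(t$value)
      if (is.list(r)) return(list(kind = "blank", value = r$iri))
      if (t$value %in% c("true", "false") || grepl("^[+-]?[0-9.]+$", t$value)) {
        if (grepl(":", t$value)) {
          return(list(kind = "iri", value = r))
        }
        return(list(kind = "literal", value = t$value, lang = NA_character_))
      }
      return(list(kind = "iri", value = r))
    }
    fail(paste0("unexpected token '", t$value, "'"))
  }

  emit <- function(s, p, o) {
    trip_s[length(trip_s) + 1L] <<- s
    trip_p[length(trip_p) + 1L] <<- p
    trip_o[length(trip_o) + 1L] <<- o$value
    trip_k[length(trip_k) + 1L] <<- o$kind
    attr_lang <- if (!is.null(o$lang)) o$lang else NA_character_
    trip_lang[length(trip_lang) + 1L] <<- attr_lang
  }
  trip_lang <- character()

  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "name" && tolower(t$value) %in% c("@prefix", "prefix")) {
      advance()
      pt <- peek(); advance()
      it <- peek(); advance()
      if (is.null(pt) || is.null(it) || it$type != "iri") fail("malformed prefix directive")
      pfx <- sub(":$", "", pt$value)
      prefixes[[paste0("p_", pfx)]] <- it$value
      if (!is.null(peek()) && peek()$type == ".") advance()
      next
    }
    if (t$type == "name" && tolower(t$value) %in% c("@base", "base")) {
      advance()
      it <- peek(); advance()
      if (is.null(it) || it$type != "iri") fail("malformed base directive")
      base <- it$value
      if (!is.null(peek()) && peek()$type == ".") advance()
      next
    }

    subj <- read_term()
    if (subj$kind == "literal") fail("literal cannot be a subject")
    repeat {
      pred <- read_term()
      if (pred$kind != "iri") fail("predicate must be an IRI")
      repeat {
        obj <- read_term()
        if (subj$kind == "iri") emit(subj$value, pred$value, obj)
        nt <- peek()
        if (!is.null(nt) && nt$type == ",") { advance(); next }
        break
      }
      nt <- peek()
      if (!is.null(nt) && nt$type == ";") {
        advance()
        # allow trailing ';' before '.'
        nt2 <- peek()
        if (!is.null(nt2) && nt2$type == ".") break
        next
      }
      break
    }
    nt <- peek()
    if (is.null(nt) || nt$type != ".") fail("expected '.' at end of statement")
    advance()
  }

  data.frame(
    subject = trip_s, predicate = trip_p, object = trip_o,
    kind = trip_k, lang = trip_lang, stringsAsFactors = FALSE
  )
}

# Assemble raw_terms from an ordered triple table.
parse_turtle_terms <- function(path, source) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  tr <- ttl_triples(text, source = source)
  if (nrow(tr) == 0) return(list())

  declared <- unique(tr$subject[tr$predicate == IRI_RDF_TYPE & tr$object == IRI_OWL_CLASS & tr$kind == "iri"])
  subj_order <- unique(tr$subject)
  keep <- subj_order[subj_order %in% declared]

  lapply(keep, function(iri) {
    rows <- tr[tr$subject == iri, , drop = FALSE]
    sup <- rows$object[rows$predicate == IRI_RDFS_SUBCLASSOF & rows$kind == "iri"]
    labs <- rows[rows$predicate == IRI_RDFS_LABEL & rows$kind == "literal", , drop = FALSE]
    label <- NA_character_
    if (nrow(labs)) {
      en <- which(!is.na(labs$lang) & labs$lang == "en")
      label <- if (length(en)) labs$object[en[1]] else labs$object[1]
    }
    syns <- unlist(lapply(SYNONYM_IRIS, function(p) {
      rows$object[rows$predicate == p & rows$kind == "literal"]
    }), use.names = FALSE)
    defs <- rows$object[rows$predicate == IRI_OBO_DEFINITION & rows$kind == "literal"]
    depr <- rows$object[rows$predicate == IRI_OWL_DEPRECATED]
    new_raw_term(
      iri = iri, label = label,
      synonyms = if (length(syns)) unique(syns) else character(),
      definition = if (length(defs)) defs[1] else NA_character_,
      deprecated = length(depr) > 0 && tolower(depr[1]) %in% c("true", "1"),
      superclass_iris = unique(sup)
    )
  })
}
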