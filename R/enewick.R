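# eNewick serialisation of rooted networks: each reticulation gets a hybrid
# tag #H1..#Hk; the hybrid vertex is written once with its subtree and once
# (or more) as a bare #Hk reference.

#' Write a rooted network as an eNewick string
#'
#' @param rooted a `rooted_net` (see [root_network()]).
#' @return length-1 character, e.g. `"((a,(b)#H1),(#H1,c));"`.
#' @export
write_enewick <- function(rooted) {
  ed <- rooted$edges
  taxa_of <- setNames(names(rooted$labels), rooted$labels)
  rets <- as.integer(names(which(table(ed$child) == 2L)))
  htag <- setNames(paste0("#H", seq_along(rets)), rets)
  expanded <- character() # hybrid ids already written in full
  rec <- function(v) {
    tag <- htag[as.character(v)]
    if (!is.na(tag)) {
      if (as.character(v) %in% expanded) return(unname(tag))
      expanded <<- c(expanded, as.character(v))
      kids <- ed$child[ed$parent == v]
      return(paste0("(", paste(vapply(kids, rec, ""), collapse = ","),
                    ")", tag))
    }
    lab <- taxa_of[as.character(v)]
    kids <- ed$child[ed$parent == v]
    if (!length(kids)) return(unname(lab))
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")",
           if (!is.na(lab)) lab else "")
  }
  paste0(rec(rooted$root), ";")
}

#' Parse an eNewick string into a rooted network
#'
#' Supports the common dialect with `#H<k>` hybrid tags (each appearing once
#' expanded and once or more as a reference); branch lengths (`:x`) are
#' accepted and discarded.
#'
#' @param text a single eNewick string.
#' @return a `rooted_net`.
#' @export
read_enewick <- function(text) {
  s <- gsub("\\s", "", text)
  if (!nchar(s) || substring(s, nchar(s)) != ";")
    stop("eNewick parse error: missing terminating ';'")
  s <- substring(s, 1L, nchar(s) - 1L)
  pos <- 1L
  nv <- 0L
  edges <- data.frame(parent = integer(), child = integer())
  labels <- integer(0)
  hybrids <- new.env(parent = emptyenv()) # tag -> vertex id
  peek <- function() if (pos <= nchar(s)) substring(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  perr <- function(msg) stop("eNewick parse error at character ", pos, ": ", msg)
  read_name <- function() {
    start <- pos
    while (pos <= nchar(s) && !peek() %in% c("(", ")", ",", ":", ";"))
      advance()
    substring(s, start, pos - 1L)
  }
  new_vertex <- function() { nv <<- nv + 1L; nv }
  # returns vertex id
  parse_node <- function() {
    kids <- integer()
    if (peek() == "(") {
      advance()
      repeat {
        kids <- c(kids, parse_node())
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        perr("expected ',' or ')'")
      }
    }
    nm <- read_name()
    if (peek() == ":") { advance(); read_name() } # discard branch length
    htag <- NULL
    if (grepl("#", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "#", fixed = TRUE)[[1]]
      htag <- paste0("#", parts[length(parts)])
      nm <- parts[1]
    }
    if (!is.null(htag)) {
      v <- get0(htag, envir = hybrids)
      if (is.null(v)) { v <- new_vertex(); assign(htag, v, envir = hybrids) }
    } else {
      v <- new_vertex()
    }
    for (k in kids)
      edges <<- rbind(edges, data.frame(parent = v, child = k))
    if (nzchar(nm)) {
      if (nm %in% names(labels)) perr(paste0("duplicate taxon '", nm, "'"))
      labels[nm] <<- v
    }
    v
  }
  root <- parse_node()
  if (pos <= nchar(s)) perr("trailing characters")
  rn <- structure(list(edges = edges, root = root, labels = labels),
                  class = "rooted_net")
  indeg <- table(edges$child)
  if (any(indeg > 2L)) stop("eNewick parse error: vertex with in-degree > 2")
  rn
}

#' Read semi-directed networks from an eNewick file
#'
#' One network per line; rooted networks are read and converted to their
#' semi-directed topologies.
#'
#' @param path file path.
#' @return a list of `sdnet` objects.
#' @export
read_enewick_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) as_semidirected(read_enewick(ln)))
}

#' Write networks to an eNewick file
#'
#' Semi-directed networks are rooted first (at the outgroup if given,
#' otherwise at an arbitrary valid edge).
#'
#' @param nets an `sdnet`/`rooted_net` or list of them.
#' @param path file path.
#' @param outgroup optional taxon used to root semi-directed networks.
#' @return `path`, invisibly.
#' @export
write_enewick_file <- function(nets, path, outgroup = NULL) {
  if (inherits(nets, c("sdnet", "rooted_net"))) nets <- list(nets)
  lines <- vapply(nets, function(x) {
    if (inherits(x, "sdnet")) x <- root_network(x, outgroup = outgroup)
    write_enewick(x)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
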