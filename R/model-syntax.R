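#' Parse a population model written in lavaan-dialect syntax
#'
#' Reads a population model for a quadratic/interaction structural equation
#' model (QISEM) from a text string. The supported operator subset is
#' `=~` (measured by), `~` (regressed on), `~~` ((co)variance) and `:`
#' (product of two latent variables, `Xi1:Xi1` for a quadratic term).
#' Every right-hand-side entry must carry a numeric population value via
#' premultiplication (`0.5*Xi1`); free (unvalued) parameters are rejected
#' because the model is used to simulate data. Comments start with `#`,
#' statements are separated by newlines or `;`, and whitespace is ignored.
#'
#' All variances and covariances that the simulation needs — variances of
#' exogenous latents, structural residual variances of endogenous latents,
#' and measurement-error variances of every indicator — must be stated
#' explicitly with `~~`. Means and intercepts default to 0 and can be set
#' with `Eta1 ~ 0.3*1`.
#'
#' @param text Model syntax as a single character string.
#' @return An object of class `qisem_model`: a list with elements
#'   `latents`, `exogenous`, `endogenous`, `order` (topological),
#'   `measurement` (per-latent data frame of indicators and loadings),
#'   `equations` (per-endogenous data frame of terms `v1`, `v2` — `v2` is
#'   `NA` for linear terms — and coefficients), `variances` (named numeric,
#'   names `"a~~b"` in canonical order), `means` (named numeric) and
#'   `indicators` (all indicator names in declaration order).
#' @examples
#' spec <- parse_model("
#'   F  =~ 1*y1 + 0.8*y2
#'   y1 ~~ 0.5*y1
#'   y2 ~~ 0.5*y2
#'   F  ~~ 1*F
#' ")
#' spec$latents
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- unlist(strsplit(text, "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- gsub("[[:space:]]+", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty model syntax")

  meas <- list()   # latent -> data.frame(indicator, loading)
  eqs  <- list()   # latent -> data.frame(v1, v2, coef)
  vars <- list()   # list of (lhs, rhs, value)
  means <- numeric(0)

  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed statement: ", ln)
      lhs <- parts[1]
      for (tm in strsplit(parts[2], "+", fixed = TRUE)[[1]]) {
        pv <- .split_premultiplier(tm, ln)
        if (grepl(":", pv$name, fixed = TRUE))
          stop("product terms are not allowed in measurement statements: ", ln)
        meas[[lhs]] <- rbind(meas[[lhs]],
                             data.frame(indicator = pv$name, loading = pv$value))
      }
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "~~", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed statement: ", ln)
      pv <- .split_premultiplier(parts[2], ln)
      vars[[length(vars) + 1L]] <- list(lhs = parts[1], rhs = pv$name,
                                        value = pv$value)
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "~", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed statement: ", ln)
      lhs <- parts[1]
      for (tm in strsplit(parts[2], "+", fixed = TRUE)[[1]]) {
        pv <- .split_premultiplier(tm, ln)
        if (pv$name == "1") {
          means[lhs] <- pv$value
        } else if (grepl(":", pv$name, fixed = TRUE)) {
          vv <- strsplit(pv$name, ":", fixed = TRUE)[[1]]
          if (length(vv) != 2L) stop("only two-way products are supported: ", ln)
          eqs[[lhs]] <- rbind(eqs[[lhs]],
                              data.frame(v1 = vv[1], v2 = vv[2], coef = pv$value))
        } else {
          eqs[[lhs]] <- rbind(eqs[[lhs]],
                              data.frame(v1 = pv$name, v2 = NA_character_,
                                         coef = pv$value))
        }
      }
    } else {
      stop("statement has no recognized operator (=~, ~, ~~): ", ln)
    }
  }

  latents <- names(meas)
  indicators <- unlist(lapply(meas, function(m) m$indicator), use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("indicator(s) assigned to more than one latent: ",
         paste(unique(indicators[duplicated(indicators)]), collapse = ", "))
  if (any(names(eqs) %in% indicators))
    stop("indicators cannot appear on the left of a regression")

  ## structural variables must be declared latents
  used <- unique(c(names(eqs),
                   unlist(lapply(eqs, function(e) c(e$v1, e$v2)), use.names = FALSE)))
  used <- used[!is.na(used)]
  undecl <- setdiff(used, latents)
  if (length(undecl))
    stop("undeclared variable(s) in structural model: ",
         paste(undecl, collapse = ", "))

  endogenous <- names(eqs)
  exogenous  <- setdiff(latents, endogenous)

  ## acyclicity / topological order of the structural graph
  order <- .topo_sort(latents, eqs)

  ## variance bookkeeping with canonical pair names
  allvars <- c(latents, indicators)
  variances <- numeric(0)
  for (v in vars) {
    if (!(v$lhs %in% allvars) || !(v$rhs %in% allvars))
      stop("(co)variance statement names unknown variable: ",
           v$lhs, "~~", v$rhs)
    key <- .vkey(v$lhs, v$rhs, allvars)
    variances[key] <- v$value
  }
  missing <- character(0)
  for (v in c(latents, indicators)) {
    if (is.na(variances[.vkey(v, v, allvars)])) missing <- c(missing, v)
  }
  if (length(missing))
    stop("all (residual) variances must be stated; missing for: ",
         paste(missing, collapse = ", "))
  diag_keys <- vapply(allvars, function(v) .vkey(v, v, allvars), "")
  bad <- allvars[variances[diag_keys] < 0]
  if (length(bad))
    stop("negative variance stated for: ", paste(bad, collapse = ", "))
  lat_diag <- variances[vapply(latents, function(v) .vkey(v, v, allvars), "")]
  if (any(lat_diag <= 0))
    stop("latent variances must be > 0: ",
         paste(latents[lat_diag <= 0], collapse = ", "))
  ## covariances across the exogenous/endogenous divide are not meaningful here
  for (v in vars) {
    if (v$lhs != v$rhs) {
      both_lat <- v$lhs %in% latents && v$rhs %in% latents
      if (both_lat) {
        mix <- xor(v$lhs %in% exogenous, v$rhs %in% exogenous)
        if (mix)
          stop("covariance between an exogenous latent and a structural ",
               "residual is not supported: ", v$lhs, "~~", v$rhs)
      } else if (!(v$lhs %in% indicators && v$rhs %in% indicators)) {
        stop("covariance must pair two latents or two indicators: ",
             v$lhs, "~~", v$rhs)
      }
    }
  }

  spec <- structure(list(
    latents = latents,
    exogenous = exogenous,
    endogenous = endogenous,
    order = order,
    measurement = meas,
    equations = eqs,
    variances = variances,
    means = means,
    indicators = indicators
  ), class = "qisem_model")

  ## exogenous covariance matrix must be positive definite
  if (length(exogenous)) {
    phi <- .latent_block(spec, exogenous)
    ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("covariance matrix of exogenous latents is not positive definite")
  }
  spec
}

.split_premultiplier <- function(term, ln) {
  pos <- regexpr("*", term, fixed = TRUE)
  if (pos < 0)
    stop("population value required (use value*name): '", term, "' in: ", ln)
  val <- suppressWarnings(as.numeric(substr(term, 1L, pos - 1L)))
  if (is.na(val))
    stop("non-numeric premultiplier in: ", ln)
  name <- substr(term, pos + 1L, nchar(term))
  if (!nzchar(name)) stop("malformed term in: ", ln)
  list(value = val, name = name)
}

.vkey <- function(a, b, ordering) {
  ia <- match(a, ordering); ib <- match(b, ordering)
  if (ia <= ib) paste0(a, "~~", b) else paste0(b, "~~", a)
}

.topo_sort <- function(latents, eqs) {
  parents <- lapply(latents, function(l) {
    e <- eqs[[l]]
    if (is.null(e)) character(0)
    else unique(stats::na.omit(c(e$v1, e$v2)))
  })
  names(parents) <- latents
  order <- character(0)
  remaining <- latents
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(l)
      all(parents[[l]] %in% order), TRUE)]
    if (!length(ready))
      stop("structural system is cyclic (involves: ",
           paste(remaining, collapse = ", "), ")")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

## symmetric value matrix over a set of latents from declared (co)variances
.latent_block <- function(spec, vars) {
  k <- length(vars)
  m <- matrix(0, k, k, dimnames = list(vars, vars))
  allv <- c(spec$latents, spec$indicators)
  for (i in seq_len(k)) for (j in seq_len(i)) {
    v <- spec$variances[.vkey(vars[i], vars[j], allv)]
    if (!is.na(v)) m[i, j] <- m[j, i] <- v
  }
  m
}

#' Canonical label of a structural term
#'
#' Products are order-insensitive (`Xi1:Xi2` and `Xi2:Xi1` address the same
#' coefficient); the canonical label sorts the two components by their
#' declaration order in the model.
#' @param v1,v2 Latent names; `v2` may be `NA` for a linear term.
#' @param spec The parsed model (used for declaration order).
#' @return A character label, e.g. `"Xi1"` or `"Xi1:Xi2"`.
#' @keywords internal
term_label <- function(v1, v2, spec) {
  if (is.na(v2)) return(v1)
  o <- match(c(v1, v2), spec$latents)
  if (o[1] <= o[2]) paste0(v1, ":", v2) else paste0(v2, ":", v1)
}

#' Resolve a parameter-of-interest string
#'
#' @param poi A string such as `"Eta1 ~ Xi1:Xi2"` (spaces ignored; product
#'   order irrelevant).
#' @param spec A `qisem_model`.
#' @return A list with `lhs` (the endogenous latent) and `term` (canonical
#'   term label); errors if the address does not resolve to exactly one
#'   coefficient, listing the available parameters.
#' @export
resolve_poi <- function(poi, spec) {
  s <- gsub("[[:space:]]+", "", poi)
  parts <- strsplit(s, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("POI must have the form 'Eta ~ term': ", poi)
  lhs <- parts[1]
  avail <- structural_parameters(spec)
  if (!(lhs %in% spec$endogenous))
    stop("'", lhs, "' has no structural equation; available parameters: ",
         paste(avail, collapse = ", "))
  vv <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
  lbl <- if (length(vv) == 2L && all(vv %in% spec$latents))
    term_label(vv[1], vv[2], spec) else parts[2]
  key <- paste0(lhs, "~", lbl)
  if (!(key %in% avail))
    stop("POI '", poi, "' not found; available parameters: ",
         paste(avail, collapse = ", "))
  list(lhs = lhs, term = lbl, key = key)
}

#' List the structural coefficient addresses of a model
#' @param spec A `qisem_model`.
#' @return Character vector of `"Eta~term"` keys in declaration order.
#' @export
structural_parameters <- function(spec) {
  unlist(lapply(spec$endogenous, function(l) {
    e <- spec$equations[[l]]
    paste0(l, "~", vapply(seq_len(nrow(e)),
                          function(i) term_label(e$v1[i], e$v2[i], spec), ""))
  }), use.names = FALSE)
}

#' Serialize a parsed model back to canonical syntax
#'
#' `parse_model(serialize_model(spec))` reproduces `spec` exactly.
#' @param spec A `qisem_model`.
#' @return A single character string of model syntax.
#' @export
serialize_model <- function(spec) {
  out <- character(0)
  for (l in names(spec$measurement)) {
    m <- spec$measurement[[l]]
    out <- c(out, paste0(l, " =~ ",
                         paste0(m$loading, "*", m$indicator, collapse = " + ")))
  }
  for (l in names(spec$equations)) {
    e <- spec$equations[[l]]
    rhs <- vapply(seq_len(nrow(e)), function(i) {
      nm <- if (is.na(e$v2[i])) e$v1[i] else paste0(e$v1[i], ":", e$v2[i])
      paste0(e$coef[i], "*", nm)
    }, "")
    out <- c(out, paste0(l, " ~ ", paste(rhs, collapse = " + ")))
  }
  for (k in names(spec$variances)) {
    pair <- strsplit(k, "~~", fixed = TRUE)[[1]]
    out <- c(out, paste0(pair[1], " ~~ ", spec$variances[[k]], "*", pair[2]))
  }
  for (v in names(spec$means)) {
    out <- c(out, paste0(v, " ~ ", spec$means[[v]], "*1"))
  }
  paste(out, collapse = "\n")
}

#' @export
print.qisem_model <- function(x, ...) {
  cat("QISEM population model\n")
  cat("  latents:   ", paste(x$latents, collapse = ", "), "\n")
  cat("  indicators:", length(x$indicators), "\n")
  for (l in x$endogenous) {
    e <- x$equations[[l]]
    rhs <- vapply(seq_len(nrow(e)), function(i)
      paste0(e$coef[i], "*", term_label(e$v1[i], e$v2[i], x)), "")
    cat("  ", l, "~", paste(rhs, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Count the free parameters a fitting method estimates
#'
#' Used for the default sample-size bounds of the adaptive search,
#' `n_lb = 5 * #par` and `n_start = 10 * #par`. For the path-model methods
#' (`SR`, `FSR`) the count covers, per structural equation, the slopes, the
#' intercept and the residual variance. For `UPI` the count enumerates the
#' augmented linear SEM: free loadings (first indicator fixed per latent),
#' measurement-error variances, structural coefficients, residual variances,
#' and the free (co)variances of the exogenous block including the latent
#' product factors; single-indicator latents contribute no measurement
#' parameters (their loading and error variance are fixed).
#'
#' @param spec A `qisem_model`.
#' @param method One of `"SR"`, `"FSR"`, `"UPI"`.
#' @return Integer count of free parameters.
#' @export
count_parameters <- function(spec, method = c("SR", "FSR", "UPI")) {
  method <- match.arg(method)
  n_eq <- sum(vapply(spec$equations, nrow, 0L))
  if (method %in% c("SR", "FSR"))
    return(as.integer(n_eq + 2L * length(spec$endogenous)))
  ## UPI augmented model
  count <- 0L
  for (l in spec$latents) {
    k <- nrow(spec$measurement[[l]])
    if (k > 1L) count <- count + (k - 1L) + k        # free loadings + thetas
  }
  prods <- .product_terms(spec)
  for (p in prods) {
    kA <- nrow(spec$measurement[[p[1]]])
    kB <- nrow(spec$measurement[[p[2]]])
    k <- min(kA, kB)                                  # matched product indicators
    if (k > 1L) count <- count + (k - 1L) + k
  }
  q <- length(spec$exogenous) + length(prods)        # exogenous block incl products
  count <- count + q * (q + 1L) %/% 2L
  count <- count + n_eq + length(spec$endogenous)    # structural + residual vars
  ## declared residual covariances between endogenous latents
  for (k in names(spec$variances)) {
    pair <- strsplit(k, "~~", fixed = TRUE)[[1]]
    if (pair[1] != pair[2] && all(pair %in% spec$endogenous))
      count <- count + 1L
  }
  as.integer(count)
}

## distinct product terms across all equations, as canonical pairs
.product_terms <- function(spec) {
  seen <- character(0)
  out <- list()
  for (l in spec$endogenous) {
    e <- spec$equations[[l]]
    for (i in seq_len(nrow(e))) {
      if (!is.na(e$v2[i])) {
        lbl <- term_label(e$v1[i], e$v2[i], spec)
        if (!(lbl %in% seen)) {
          seen <- c(seen, lbl)
          out[[lbl]] <- strsplit(lbl, ":", fixed = TRUE)[[1]]
        }
      }
    }
  }
  out
}
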