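#' Contrast specification
#'
#' A named weight vector aligned to the columns of a design matrix.  Weights
#' on columns not mentioned are zero.  At least one weight must be nonzero.
#'
#' @param weights Named numeric vector (names are design column names), or an
#'   unnamed vector already aligned to `column_names`.
#' @param column_names Character vector of design column names to align to.
#' @param name Optional label for the contrast.
#' @return An object of class `contrast_spec`: numeric vector of length
#'   `length(column_names)` with a `name` attribute.
#' @export
contrast_spec <- function(weights, column_names, name = NULL) {
  w <- numeric(length(column_names))
  names(w) <- column_names
  if (!is.null(names(weights)) && any(names(weights) != "")) {
    unknown <- setdiff(names(weights), column_names)
    if (length(unknown) > 0) {
      stop(sprintf("unknown column(s) %s; available: %s",
                   paste(unknown, collapse = ", "),
                   paste(column_names, collapse = ", ")), call. = FALSE)
    }
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(column_names)) {
      stop("unnamed weights must match the number of design columns",
           call. = FALSE)
    }
    w[] <- weights
  }
  if (all(w == 0)) stop("contrast has no nonzero weight", call. = FALSE)
  structure(w, name = if (is.null(name)) "contrast" else name,
            class = "contrast_spec")
}

#' Parse a contrast expression
#'
#' Parses a signed weighted sum of column names, e.g.
#' `"Cue_LargeWin - Cue_Neutral"` or
#' `"0.5*FB_LargeWin_Hit + 0.5*FB_SmallWin_Hit - 0.5*FB_LargeWin_Miss - 0.5*FB_SmallWin_Miss"`.
#'
#' @param expression Character scalar.
#' @param column_names Design column names to align the weights to.
#' @param name Optional contrast label (defaults to the expression).
#' @return A [contrast_spec()].
#' @export
parse_contrast <- function(expression, column_names, name = expression) {
  s <- gsub("\\s+", "", expression)
  if (!nzchar(s)) stop("empty contrast expression", call. = FALSE)
  if (!grepl("^[+-]", s)) s <- paste0("+", s)
  m <- gregexpr("[+-][^+-]+", s)[[1]]
  terms <- regmatches(s, gregexpr("[+-][^+-]+", s))[[1]]
  if (sum(nchar(terms)) != nchar(s)) {
    stop(sprintf("cannot parse contrast expression '%s'", expression),
         call. = FALSE)
  }
  w <- numeric(0)
  for (term in terms) {
    sign <- if (substr(term, 1, 1) == "-") -1 else 1
    body <- substring(term, 2)
    if (grepl("\\*", body)) {
      parts <- strsplit(body, "\\*", fixed = FALSE)[[1]]
      coef <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(coef)) stop(sprintf("bad coefficient in term '%s'", term),
                            call. = FALSE)
      nm <- parts[2]
    } else if (grepl("^[0-9.]+[A-Za-z_]", body)) {
      coef <- as.numeric(regmatches(body, regexpr("^[0-9.]+", body)))
      nm <- sub("^[0-9.]+", "", body)
    } else {
      coef <- 1
      nm <- body
    }
    if (!nm %in% column_names) {
      cand <- column_names[order(utils::adist(nm, column_names))]
      stop(sprintf("unknown column '%s' in contrast; candidates: %s", nm,
                   paste(utils::head(cand, 5), collapse = ", ")),
           call. = FALSE)
    }
    w[nm] <- (if (nm %in% names(w)) w[[nm]] else 0) + sign * coef
  }
  contrast_spec(w, column_names, name = name)
}

#' @export
print.contrast_spec <- function(x, ...) {
  nz <- x[x != 0]
  cat(sprintf("<contrast_spec> %s: %s\n", attr(x, "name"),
              paste(sprintf("%+g*%s", unname(nz), names(nz)),
                    collapse = " ")))
  invisible(x)
}

# coerce a contrast (spec / named vector / numeric) to a plain vector aligned
# with the design's columns
align_contrast <- function(design, c) {
  cn <- design$column_names
  if (inherits(c, "contrast_spec")) {
    if (length(c) != length(cn)) {
      # allow specs defined over task columns only
      if (length(c) == length(design$task_cols) &&
          identical(names(c), cn[design$task_cols])) {
        w <- numeric(length(cn))
        names(w) <- cn
        w[names(c)] <- c
        return(w)
      }
      stop("contrast length does not match the design", call. = FALSE)
    }
    return(stats::setNames(as.numeric(c), names(c)))
  }
  as.numeric(contrast_spec(c, cn))
}
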