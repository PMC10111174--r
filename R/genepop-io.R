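#' Read a GenePop file
#'
#' Parses the classic GenePop layout: a title line, one locus name per line
#' (or a single comma-separated line), then `Pop` blocks of
#' `id , g1 g2 ...` rows where each genotype is a 4- or 6-digit code made of
#' two 2- or 3-digit allele states. All-zero codes (`0000` / `000000`)
#' are read as missing; half-missing codes are a parse error.
#'
#' @param path path to a GenePop text file
#' @param dialect `"3-digit"` (default) or `"2-digit"`; when `NULL` the
#'   width is inferred from the first genotype code.
#' @param pop_names optional character vector naming the populations in
#'   file order; defaults to the id of the last individual of each block,
#'   the GenePop convention, made unique.
#' @return a [genotype_matrix()]
#' @export
read_genepop <- function(path, dialect = c("3-digit", "2-digit"),
                         pop_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 4L) stop("not a GenePop file: too few lines")
  body <- lines[-1L]                       # drop title
  pop_rows <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_rows)) stop("no 'Pop' line found")
  loc_lines <- body[seq_len(pop_rows[1L] - 1L)]
  loci_names <- unlist(strsplit(loc_lines, "\\s*,\\s*"))
  loci_names <- trimws(loci_names[nzchar(trimws(loci_names))])
  L <- length(loci_names)
  if (!L) stop("no locus names before the first 'Pop' line")

  width <- NULL
  if (!is.null(dialect)) {
    dialect <- match.arg(dialect)
    width <- if (dialect == "3-digit") 3L else 2L
  }
  block_of <- findInterval(seq_along(body), pop_rows)
  ids <- character(0); pops <- integer(0)
  A1 <- NULL; A2 <- NULL
  for (i in seq_along(body)) {
    if (i <= pop_rows[1L] - 1L || i %in% pop_rows) next
    ln <- body[i]
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop("malformed GenePop individual line ", i + 1L, ": no comma")
    id <- trimws(parts[1L])
    codes <- strsplit(trimws(paste(parts[-1L], collapse = " ")),
                      "\\s+")[[1L]]
    if (length(codes) != L)
      stop("line ", i + 1L, ": expected ", L, " genotypes, found ",
           length(codes))
    if (is.null(width)) {
      nc <- nchar(codes[1L])
      width <- if (nc == 4L) 2L else if (nc == 6L) 3L else
        stop("line ", i + 1L, ": cannot infer digit width from code '",
             codes[1L], "'")
    }
    if (any(nchar(codes) != 2L * width))
      stop("line ", i + 1L, ": genotype code width differs from ",
           2L * width, " digits")
    x1 <- as.integer(substr(codes, 1L, width))
    x2 <- as.integer(substr(codes, width + 1L, 2L * width))
    if (any(is.na(x1)) || any(is.na(x2)))
      stop("line ", i + 1L, ": non-numeric genotype code")
    if (any(xor(x1 == 0L, x2 == 0L)))
      stop("line ", i + 1L, ": half-missing genotype code")
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, block_of[i])
    A1 <- rbind(A1, x1); A2 <- rbind(A2, x2)
  }
  if (!length(ids)) stop("no individuals found")
  if (is.null(pop_names)) {
    pop_names <- vapply(split(ids, pops), function(v) v[length(v)], "")
    pop_names <- make.unique(pop_names)
  }
  if (length(pop_names) != length(unique(pops)))
    stop("pop_names length does not match the number of Pop blocks")
  colnames(A1) <- colnames(A2) <- loci_names
  gm <- genotype_matrix(A1, A2, pop = pop_names[pops],
                        ind = make.unique(ids))
  gm$pop <- factor(as.character(gm$pop), levels = pop_names)
  gm
}

#' Write a GenePop file
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @param dialect `"3-digit"` (default; allele sizes above 99 overflow the
#'   2-digit dialect) or `"2-digit"`
#' @param title title line content
#' @return `path`, invisibly
#' @export
write_genepop <- function(gm, path, dialect = c("3-digit", "2-digit"),
                          title = "msatcoal export") {
  dialect <- match.arg(dialect)
  width <- if (dialect == "3-digit") 3L else 2L
  if (n_ind(gm) < 1L) stop("cannot write an empty genotype matrix")
  mx <- max(c(gm$a1, gm$a2), na.rm = TRUE)
  if (mx > 10^width - 1)
    stop("allele state ", mx, " does not fit the ", dialect, " dialect")
  fmt <- function(m) {
    v <- ifelse(is.na(m), 0L, m)
    matrix(formatC(v, width = width, flag = "0"), nrow = nrow(m))
  }
  c1 <- fmt(gm$a1); c2 <- fmt(gm$a2)
  codes <- matrix(paste0(c1, c2), nrow = n_ind(gm))
  out <- c(title, gm$loci$name)
  for (p in levels(gm$pop)) {
    rows <- which(gm$pop == p)
    if (!length(rows)) next
    out <- c(out, "Pop",
             paste0(gm$ind[rows], " , ",
                    apply(codes[rows, , drop = FALSE], 1, paste,
                          collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write the CSV genotype dialect
#'
#' One row per individual: `id`, `pop`, then two columns per locus
#' (`<locus>_1`, `<locus>_2`). Blank or zero cells are missing. The column
#' layout is configurable through `id_col`, `pop_col` and `locus_cols` so
#' that externally produced tables can be adapted.
#'
#' @param path CSV path
#' @param id_col,pop_col column names of the individual id and population
#'   label
#' @param locus_cols optional character vector of the 2L allele columns, in
#'   locus order; defaults to all remaining columns
#' @return a [genotype_matrix()]
#' @export
read_genotypes_csv <- function(path, id_col = "id", pop_col = "pop",
                               locus_cols = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c(id_col, pop_col) %in% names(df)))
    stop("missing id/pop columns: ", id_col, ", ", pop_col)
  if (is.null(locus_cols))
    locus_cols <- setdiff(names(df), c(id_col, pop_col))
  if (length(locus_cols) %% 2L != 0L)
    stop("odd number of allele columns")
  L <- length(locus_cols) %/% 2L
  m <- as.matrix(df[, locus_cols, drop = FALSE])
  storage.mode(m) <- "integer"
  m[m == 0L] <- NA_integer_
  a1 <- m[, 2L * seq_len(L) - 1L, drop = FALSE]
  a2 <- m[, 2L * seq_len(L), drop = FALSE]
  colnames(a1) <- colnames(a2) <-
    sub("_[12]$", "", locus_cols[2L * seq_len(L) - 1L])
  genotype_matrix(a1, a2, pop = df[[pop_col]], ind = df[[id_col]])
}

#' @rdname read_genotypes_csv
#' @param gm a [genotype_matrix()]
#' @export
write_genotypes_csv <- function(gm, path) {
  L <- n_loci(gm)
  out <- data.frame(id = gm$ind, pop = as.character(gm$pop),
                    check.names = FALSE)
  for (j in seq_len(L)) {
    out[[paste0(gm$loci$name[j], "_1")]] <- gm$a1[, j]
    out[[paste0(gm$loci$name[j], "_2")]] <- gm$a2[, j]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "0")
  invisible(path)
}

#' Parse a degrees-minutes coordinate string to decimal degrees
#'
#' Accepts forms like `60°31'`, `60 31`, `60d31m`, optionally with a
#' trailing hemisphere letter, or a plain decimal number.
#'
#' @param x character vector
#' @return numeric decimal degrees
#' @export
parse_dms <- function(x) {
  out <- vapply(as.character(x), function(s) {
    s0 <- trimws(s)
    if (grepl("^[-+]?[0-9.]+$", s0)) return(as.numeric(s0))
    sgn <- if (grepl("[SWsw]\\s*$", s0) || grepl("^-", s0)) -1 else 1
    num <- regmatches(s0, gregexpr("[0-9]+(\\.[0-9]+)?", s0))[[1L]]
    if (!length(num) || length(num) > 3L)
      stop("cannot parse coordinate '", s, "'")
    num <- as.numeric(num)
    deg <- num[1L]
    if (length(num) >= 2L) deg <- deg + num[2L] / 60
    if (length(num) == 3L) deg <- deg + num[3L] / 3600
    sgn * deg
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Read a site table
#'
#' Delimited table with at least `site_code`, `latitude`, `longitude`
#' columns; coordinates may be decimal degrees or degrees-minutes strings
#' (converted with [parse_dms()]). Optional columns `sample_year`,
#' `cluster_id` and `n` are carried through.
#'
#' @param path CSV path
#' @return a data frame of class `site_table`
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  req <- c("site_code", "latitude", "longitude")
  if (!all(req %in% names(df)))
    stop("site table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$site_code)) stop("site codes must be unique")
  for (cc in c("latitude", "longitude")) {
    df[[cc]] <- tryCatch(parse_dms(df[[cc]]), error = function(e)
      stop("column ", cc, ": ", conditionMessage(e)))
  }
  if (any(abs(df$latitude) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(df$longitude) > 180)) stop("longitude outside [-180, 180]")
  class(df) <- c("site_table", "data.frame")
  df
}
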