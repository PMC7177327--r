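.legal_pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")

# mirror of a stack key "XY/ZW" (duplex read from the other side)
.mirror_stack <- function(key) {
  x <- strsplit(sub("/.*", "", key), "")[[1]]
  z <- strsplit(sub(".*/", "", key), "")[[1]]
  paste0(z[2], z[1], "/", x[2], x[1])
}

#' Nearest-neighbor energy model for miRNA:target duplexes
#'
#' Loads the packaged plain-text parameter table (or a user-supplied file
#' in the same format): stacking free energies for Watson-Crick and G:U
#' pairs plus affine loop penalties (`bulge_open`/`bulge_extend` for
#' one-sided bulges, `internal_open`/`internal_extend` for two-sided
#' internal loops) and the duplex initiation cost. Wobble stacks absent
#' from the file default to `default_gu` kcal/mol; mirror-symmetric
#' entries are filled in automatically and checked for consistency. All
#' stacks must be negative and all penalties non-negative.
#'
#' @param path Parameter file; default the packaged table.
#' @param default_gu Fallback stack energy for unlisted wobble stacks.
#' @return A `perimir_energy_model`: list with `stacks` (named numeric over
#'   all legal pair combinations) and the penalty/initiation parameters.
#' @examples
#' m <- default_energy_model()
#' m$stacks[["GG/CC"]]
#' @export
default_energy_model <- function(path = NULL, default_gu = -0.5) {
  path <- path %||% system.file("extdata", "energy", "stack_energies.tsv",
    package = "perimir"
  )
  raw <- utils::read.table(path,
    sep = "\t", comment.char = "#",
    col.names = c("kind", "key", "value"), stringsAsFactors = FALSE
  )
  stacks <- setNames(
    raw$value[raw$kind == "stack"],
    raw$key[raw$kind == "stack"]
  )
  params <- setNames(
    raw$value[raw$kind == "param"],
    raw$key[raw$kind == "param"]
  )
  need <- c(
    "duplex_init", "bulge_open", "bulge_extend",
    "internal_open", "internal_extend"
  )
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    abort(paste0("energy file missing param(s): ", paste(miss, collapse = ", ")))
  }
  # expand mirrors, then default the remaining wobble stacks
  for (key in names(stacks)) {
    mk <- .mirror_stack(key)
    if (mk %in% names(stacks)) {
      if (abs(stacks[[mk]] - stacks[[key]]) > 1e-9) {
        abort(paste0("stack table not mirror-symmetric: ", key, " vs ", mk))
      }
    } else {
      stacks[[mk]] <- stacks[[key]]
    }
  }
  for (p1 in .legal_pairs) {
    for (p2 in .legal_pairs) {
      key <- paste0(
        substr(p1, 1, 1), substr(p2, 1, 1), "/",
        substr(p1, 2, 2), substr(p2, 2, 2)
      )
      if (!key %in% names(stacks)) stacks[[key]] <- default_gu
    }
  }
  if (any(stacks >= 0)) abort("all stack energies must be < 0")
  if (any(params[need] < 0)) abort("all loop/init penalties must be >= 0")
  structure(
    c(list(stacks = stacks), as.list(params[need])),
    class = "perimir_energy_model"
  )
}

#' Minimum free energy of an intermolecular miRNA:target duplex
#'
#' Dynamic program over antiparallel duplexes of the two strands (no
#' intramolecular structure): consecutive base pairs contribute
#' nearest-neighbor stacking energies, one-sided bulges and two-sided
#' internal loops carry affine penalties, dangling ends are free, and a
#' single duplex-initiation cost applies. The global optimum over all pair
#' sets with strictly monotone indices (miRNA ascending 5'-3', target
#' descending) is returned; when no duplex reaches a negative energy the
#' result is an empty pairing with `mfe = 0`.
#'
#' @param mirna miRNA sequence, RNA alphabet, 5' to 3'.
#' @param target_region Target (site) region sequence, RNA, length <= 60.
#' @param model A [default_energy_model()].
#' @param max_loop Maximum unpaired run per strand inside the duplex.
#' @return A `perimir_duplex`: `mfe` (kcal/mol), `pairing` tibble
#'   (`mirna_pos`, `target_pos`, strictly monotone), `binding_start`
#'   (1-based 5' miRNA position of the first pair, `NA` when unpaired),
#'   `alignment` (two-line text rendering).
#' @examples
#' duplex_mfe("GGGG", "CCCC")$mfe
#' @export
duplex_mfe <- function(mirna, target_region, model = default_energy_model(),
                       max_loop = 10) {
  .check_rna(mirna, "mirna")
  .check_rna(target_region, "target_region")
  n <- nchar(mirna)
  L <- nchar(target_region)
  if (n < 2 || L < 2) abort("both sequences must be at least 2 nt")
  if (L > 60) abort("target_region longer than 60 nt; pass the site region only")
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(target_region, "")[[1]]

  can_pair <- outer(m, t, function(a, b) paste0(a, b) %in% .legal_pairs)
  H <- matrix(Inf, n, L)
  P <- matrix(0L, n, L) # predecessor encoded as (p - 1) * L + q; 0 = start
  init <- model$duplex_init
  stacks <- model$stacks

  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      if (!can_pair[i, j]) next
      best <- init
      bp <- 0L
      if (i > 1L && j < L) {
        for (p in max(1L, i - 1L - max_loop):(i - 1L)) {
          for (q in (j + 1L):min(L, j + 1L + max_loop)) {
            if (!is.finite(H[p, q])) next
            a <- i - p - 1L
            b <- q - j - 1L
            cost <- if (a == 0L && b == 0L) {
              stacks[[paste0(m[p], m[i], "/", t[q], t[j])]]
            } else if (a == 0L || b == 0L) {
              model$bulge_open + model$bulge_extend * (a + b - 1L)
            } else {
              model$internal_open + model$internal_extend * (a + b - 2L)
            }
            cand <- H[p, q] + cost
            if (cand < best) {
              best <- cand
              bp <- (p - 1L) * L + q
            }
          }
        }
      }
      H[i, j] <- best
      P[i, j] <- bp
    }
  }

  mfe <- suppressWarnings(min(H))
  if (!is.finite(mfe) || mfe >= 0) {
    return(structure(
      list(
        mfe = 0,
        pairing = tibble(mirna_pos = integer(), target_pos = integer()),
        binding_start = NA_integer_,
        mirna = mirna, target = target_region, alignment = ""
      ),
      class = "perimir_duplex"
    ))
  }
  end <- which(H == mfe, arr.ind = TRUE)[1, ]
  pairs <- list()
  i <- end[["row"]]
  j <- end[["col"]]
  repeat {
    pairs[[length(pairs) + 1]] <- c(i, j)
    code <- P[i, j]
    if (code == 0L) break
    i <- (code - 1L) %/% L + 1L
    j <- (code - 1L) %% L + 1L
  }
  pairs <- rev(pairs)
  pairing <- tibble(
    mirna_pos = vapply(pairs, `[`, 0, 1),
    target_pos = vapply(pairs, `[`, 0, 2)
  )
  structure(
    list(
      mfe = mfe,
      pairing = pairing,
      binding_start = as.integer(min(pairing$mirna_pos)),
      mirna = mirna, target = target_region,
      alignment = .render_duplex(m, t, pairing)
    ),
    class = "perimir_duplex"
  )
}

# two-line text rendering: miRNA 5'->3' on top, target 3'->5' below,
# '|' between paired bases, loop gaps padded with '-'
.render_duplex <- function(m, t, pairing) {
  if (nrow(pairing) == 0) return("")
  pad <- function(x, len) {
    paste0(paste(x, collapse = ""), strrep("-", len - length(x)))
  }
  top <- m[pairing$mirna_pos[1]]
  mid <- "|"
  bot <- t[pairing$target_pos[1]]
  for (k in seq_len(nrow(pairing))[-1]) {
    i0 <- pairing$mirna_pos[k - 1]
    j0 <- pairing$target_pos[k - 1]
    i <- pairing$mirna_pos[k]
    j <- pairing$target_pos[k]
    gi <- if (i - i0 > 1) m[(i0 + 1):(i - 1)] else character()
    gj <- if (j0 - j > 1) t[(j0 - 1):(j + 1)] else character()
    len <- max(length(gi), length(gj))
    if (len > 0) {
      top <- c(top, pad(gi, len))
      mid <- c(mid, strrep(" ", len))
      bot <- c(bot, pad(gj, len))
    }
    top <- c(top, m[i])
    mid <- c(mid, "|")
    bot <- c(bot, t[j])
  }
  paste0(
    "5' ", paste(top, collapse = ""), " 3' (miRNA)\n",
    "   ", paste(mid, collapse = ""), "\n",
    "3' ", paste(bot, collapse = ""), " 5' (target)"
  )
}

#' @export
print.perimir_duplex <- function(x, ...) {
  cat("<perimir_duplex> mfe = ", signif(x$mfe, 4), " kcal/mol",
    if (nrow(x$pairing)) paste0(", binding start nt ", x$binding_start),
    "\n",
    sep = ""
  )
  if (nzchar(x$alignment)) cat(x$alignment, "\n")
  invisible(x)
}

#' 5' miRNA position where optimal duplex pairing starts
#'
#' @param result A `perimir_duplex` from [duplex_mfe()].
#' @return Integer, 1-based from the miRNA 5' end.
#' @examples
#' binding_start(duplex_mfe("GGGG", "CCCC"))
#' @export
binding_start <- function(result) {
  stopifnot(inherits(result, "perimir_duplex"))
  if (nrow(result$pairing) == 0) {
    abort("empty pairing: no favorable duplex was formed")
  }
  result$binding_start
}

#' Extract the target region around a seed site
#'
#' Returns `width` nt of the UTR centered on a seed site (clipped at the
#' UTR ends), the default context handed to [duplex_mfe()].
#'
#' @param utr UTR sequence (RNA).
#' @param site_start 1-based start of the site (from [scan_sites()]).
#' @param site_width Site length in nt (8 for an 8mer).
#' @param width Total region width, default 30.
#' @return The region substring.
#' @export
extract_site_region <- function(utr, site_start, site_width = 8, width = 30) {
  center <- site_start + floor(site_width / 2)
  from <- max(1, center - floor(width / 2))
  to <- min(nchar(utr), from + width - 1)
  substr(utr, from, to)
}

#' Duplex MFE over a set of target regions
#'
#' @param mirna miRNA sequence (RNA).
#' @param regions Named character vector of target regions.
#' @param model A [default_energy_model()].
#' @return Tibble: `id`, `mfe`, `binding_start`, `n_pairs`, `alignment`.
#' @export
duplex_table <- function(mirna, regions, model = default_energy_model()) {
  purrr::map_dfr(names(regions), function(id) {
    d <- duplex_mfe(mirna, regions[[id]], model)
    tibble(
      id = id, mfe = d$mfe,
      binding_start = if (nrow(d$pairing)) d$binding_start else NA_integer_,
      n_pairs = nrow(d$pairing),
      alignment = d$alignment
    )
  })
}
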