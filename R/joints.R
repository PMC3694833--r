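# Joint space: every candidate end-joining product supported by the two ends
# of a staggered cut, described by the (D, M, L, R, I) nomenclature.
#
# D = net base pairs lost (negative) or gained (positive) in the joint,
# M = microhomologous base pairs annealed at the junction,
# L = bases deleted from the left end, measured from the most distal
#     overhang base, R = same for the right end,
# I = 0-2 non-templated inserted bases, read from the top strand.
# The algebra ties them together: D = v - L - R - M + |I|.
#
# The repaired top strand is
#     product = top[1 .. t-L] + I + top[t-v+R+M+1 .. N]
# where t is the cut position and v the overhang length. A joint with M > 0
# is only physical when the M junction bases retained on the left equal the
# M right-end bases they stand in for:
#     top[t-L-M+1 .. t-L] == top[t-v+R+1 .. t-v+R+M].
# Insertions are restricted to M = 0 junctions: templated (microhomology)
# explanations and non-templated insertions are alternative joint classes,
# and mixing them would make joint identity unresolvable.

#' Construct a joint descriptor
#'
#' @param L,R Non-negative integers: bases deleted from the left / right end,
#'   measured from the most distal base of the overhang.
#' @param M Non-negative integer: microhomologous base pairs at the junction.
#' @param I Character scalar of 0-2 inserted bases (`""` for none); stored
#'   uppercase. Nonempty `I` requires `M == 0`.
#' @param overhang_len Overhang length `v` of the locus the descriptor refers
#'   to; needed to compute `D` and to flag the precise joint.
#' @return Object of class `joint_descriptor` with fields
#'   `D`, `M`, `L`, `R`, `I`, `is_precise`.
#' @examples
#' joint_descriptor(L = 0, R = 0, M = 4, I = "", overhang_len = 4)  # precise
#' @export
joint_descriptor <- function(L, R, M, I = "", overhang_len) {
  L <- as.integer(L); R <- as.integer(R); M <- as.integer(M)
  v <- as.integer(overhang_len)
  I <- toupper(as.character(I))
  if (is.na(I)) I <- ""
  if (L < 0L || R < 0L || M < 0L) stop("L, R, M must be >= 0")
  if (nchar(I) > 2L) stop("at most two inserted bases are allowed (|I| <= 2)")
  if (nchar(I) > 0L && grepl("[^ACGT]", I)) stop("I must be over A/C/G/T")
  if (nchar(I) > 0L && M > 0L)
    stop("insertions are only modelled at M = 0 junctions")
  D <- v - L - R - M + nchar(I)
  structure(list(D = D, M = M, L = L, R = R, I = I,
                 is_precise = (L == 0L && R == 0L && M == v && nchar(I) == 0L)),
            class = "joint_descriptor")
}

#' @export
print.joint_descriptor <- function(x, ...) {
  cat(sprintf("<joint_descriptor> %s (D=%+d, M=%d, L=%d, R=%d, I='%s')\n",
              encode_joint_id(x), x$D, x$M, x$L, x$R, x$I))
  invisible(x)
}

# is (L, R, M, I) a physically valid joint on this locus?
# Checks index bounds and the M-identity (annealing) constraint.
descriptor_valid <- function(L, R, M, I, locus) {
  t <- locus$cut_pos; v <- locus$overhang_len
  s <- locus$top_strand; n <- locus$n
  if (nchar(I) > 0L && M > 0L) return(FALSE)
  if (t - L < 0L) return(FALSE)
  rstart <- t - v + R + M + 1L
  if (rstart > n + 1L) return(FALSE)
  if (t - v + R < 0L) return(FALSE)
  if (M > 0L) {
    if (t - L - M + 1L < 1L) return(FALSE)
    if (t - v + R + M > n) return(FALSE)
    left_block <- substr(s, t - L - M + 1L, t - L)
    right_block <- substr(s, t - v + R + 1L, t - v + R + M)
    if (left_block != right_block) return(FALSE)
  }
  TRUE
}

#' Reconstruct the repaired top strand of a joint
#'
#' @param desc A [joint_descriptor].
#' @param locus A [dsb_locus].
#' @return Character scalar: the full repaired top strand, of length
#'   `nchar(top_strand) + D`.
#' @examples
#' loc <- dsb_locus("AAAACGTACGTTTT", cut_pos = 8, overhang_len = 4)
#' product_sequence(joint_descriptor(1, 0, 0, "", 4), loc)
#' @export
product_sequence <- function(desc, locus) {
  stopifnot(inherits(desc, "joint_descriptor"), inherits(locus, "dsb_locus"))
  if (desc$D != locus$overhang_len - desc$L - desc$R - desc$M + nchar(desc$I))
    stop("descriptor algebra violated (was it built for a different overhang length?)")
  if (!descriptor_valid(desc$L, desc$R, desc$M, desc$I, locus))
    stop("descriptor is not valid on this locus ",
         "(M-identity constraint or deletion bounds violated)")
  t <- locus$cut_pos; v <- locus$overhang_len; s <- locus$top_strand
  left <- if (t - desc$L >= 1L) substr(s, 1L, t - desc$L) else ""
  right_start <- t - v + desc$R + desc$M + 1L
  right <- if (right_start <= locus$n) substr(s, right_start, locus$n) else ""
  paste0(left, desc$I, right)
}

# ---- enumeration -----------------------------------------------------------

# all (L, R, M, I) quadruples within limits that are valid on the locus,
# as a data.frame; the precise joint is always present.
enumerate_descriptors <- function(locus, L_max, R_max, M_max,
                                  insertion_alphabet = c("A", "C", "G", "T")) {
  v <- locus$overhang_len
  ins <- ""
  if (length(insertion_alphabet) > 0L) {
    one <- insertion_alphabet
    two <- as.vector(outer(insertion_alphabet, insertion_alphabet, paste0))
    ins <- c("", one, two)
  }
  grid_noins <- expand.grid(L = 0:L_max, R = 0:R_max, M = 0:max(M_max, v),
                            I = "", stringsAsFactors = FALSE)
  # cap M at M_max except that the precise joint (M = v) is always retained
  grid_noins <- grid_noins[grid_noins$M <= M_max |
                             (grid_noins$M == v & grid_noins$L == 0L &
                                grid_noins$R == 0L), , drop = FALSE]
  grid_ins <- expand.grid(L = 0:L_max, R = 0:R_max, M = 0L,
                          I = setdiff(ins, ""), stringsAsFactors = FALSE)
  g <- rbind(grid_noins, grid_ins)
  ok <- vapply(seq_len(nrow(g)),
               function(i) descriptor_valid(g$L[i], g$R[i], g$M[i], g$I[i], locus),
               logical(1))
  g <- g[ok, , drop = FALSE]
  g$D <- v - g$L - g$R - g$M + nchar(g$I)
  rownames(g) <- NULL
  g
}

# canonical ordering among descriptors explaining the same product:
# max M, then min |I|, then min L, then min R (final tie-break for determinism)
canonical_order <- function(g) {
  order(-g$M, nchar(g$I), g$L, g$R)
}

#' Enumerate the joint space of a cut locus
#'
#' Generates every repair product reachable within the given deletion /
#' microhomology / insertion limits, deduplicated by product sequence. Each
#' product carries the canonical descriptor among all descriptors that explain
#' it (maximum `M`, then minimum `|I|`, then minimum `L`), its identifier, and
#' the read template expected from the sequencing layout (an `N`-masked index
#' placeholder followed by the product restricted to the amplicon window,
#' truncated to the read length). The precise religation product is always
#' included. Rows are sorted by `joint_id`.
#'
#' @param locus A [dsb_locus].
#' @param layout A [read_layout]; if `NULL`, no read templates are built.
#' @param L_max,R_max Maximum deletion from the left / right end (default 25).
#' @param M_max Maximum microhomology length (default 10).
#' @param insertion_alphabet Bases available for non-templated insertions;
#'   set to `character(0)` to disable insertion joints.
#' @return A data.frame of class `joint_space` with columns `joint_id`, `D`,
#'   `M`, `L`, `R`, `I`, `product_length`, `product`, and (with a layout)
#'   `read_template`. The locus, layout and limits travel as attributes.
#' @export
enumerate_joints <- function(locus, layout = NULL, L_max = 25L, R_max = 25L,
                             M_max = 10L,
                             insertion_alphabet = c("A", "C", "G", "T")) {
  stopifnot(inherits(locus, "dsb_locus"))
  t <- locus$cut_pos; v <- locus$overhang_len; n <- locus$n
  win <- locus$amplicon_window
  if (t - L_max < win[1])
    stop("L_max = ", L_max, " pushes the junction outside the amplicon window ",
         "(window starts at ", win[1], ")")
  g <- enumerate_descriptors(locus, L_max, R_max, M_max, insertion_alphabet)
  g$product <- vapply(seq_len(nrow(g)), function(i) {
    left <- substr(locus$top_strand, 1L, t - g$L[i])
    rs <- t - v + g$R[i] + g$M[i] + 1L
    right <- if (rs <= n) substr(locus$top_strand, rs, n) else ""
    paste0(left, g$I[i], right)
  }, character(1))

  # deduplicate by product, keeping the canonical descriptor
  g <- g[canonical_order(g), , drop = FALSE]
  g <- g[!duplicated(g$product), , drop = FALSE]
  g$product_length <- nchar(g$product)

  if (!is.null(layout)) {
    stopifnot(inherits(layout, "read_layout"))
    body_len <- layout$read_len - layout$index_len
    a_start <- win[1]
    if (any(g$product_length < a_start + body_len - 1L)) {
      bad <- g[g$product_length < a_start + body_len - 1L, , drop = FALSE]
      stop("deletion limits push products shorter than the read ",
           "(smallest product ", min(bad$product_length), " bp, read needs ",
           a_start + body_len - 1L, "); reduce L_max/R_max/M_max")
    }
    junction_end <- t - g$L + nchar(g$I)  # last product position left of the joint
    if (any(junction_end + 3L > a_start + body_len - 1L) ||
        any(t - g$L - 3L < a_start))
      stop("limits place a junction outside the read (need junction +/- 3 bases ",
           "inside [", a_start, ", ", a_start + body_len - 1L, "])")
    g$read_template <- paste0(strrep("N", layout$index_len),
                              substr(g$product, a_start, a_start + body_len - 1L))
  }

  desc <- lapply(seq_len(nrow(g)), function(i)
    joint_descriptor(g$L[i], g$R[i], g$M[i], g$I[i], v))
  g$joint_id <- vapply(desc, encode_joint_id, character(1))
  g <- g[order(g$joint_id), , drop = FALSE]
  rownames(g) <- NULL
  cols <- c("joint_id", "D", "M", "L", "R", "I", "product_length", "product",
            if (!is.null(layout)) "read_template")
  out <- g[, cols]
  attr(out, "locus") <- locus
  attr(out, "layout") <- layout
  attr(out, "limits") <- list(L_max = L_max, R_max = R_max, M_max = M_max,
                              insertion_alphabet = insertion_alphabet)
  class(out) <- c("joint_space", "data.frame")
  out
}

#' @export
print.joint_space <- function(x, ...) {
  loc <- attr(x, "locus")
  cat(sprintf("<joint_space> %d joints on '%s' (v = %d)\n",
              nrow(x), loc$name, loc$overhang_len))
  print.data.frame(utils::head(as.data.frame(x)[, setdiff(names(x),
                                                          c("product", "read_template"))], 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Canonical descriptor of a repair product
#'
#' Among all `(L, R, M, I)` quadruples within the limits that explain the
#' given product sequence, returns the canonical one: maximum `M` (templated
#' explanations beat non-templated ones), then minimum `|I|`, then minimum
#' `L`. Round-trips with [product_sequence()].
#'
#' @param product Character scalar, a full repaired top strand.
#' @param locus A [dsb_locus].
#' @param L_max,R_max,M_max,insertion_alphabet Limits, as in
#'   [enumerate_joints()].
#' @return A [joint_descriptor], or an error of class `nhejseq_unexplainable`
#'   if the product cannot be derived from the two ends within the limits.
#' @export
canonical_descriptor <- function(product, locus, L_max = 25L, R_max = 25L,
                                 M_max = 10L,
                                 insertion_alphabet = c("A", "C", "G", "T")) {
  stopifnot(inherits(locus, "dsb_locus"))
  g <- enumerate_descriptors(locus, L_max, R_max, M_max, insertion_alphabet)
  t <- locus$cut_pos; v <- locus$overhang_len; n <- locus$n
  hits <- g[v - g$L - g$R - g$M + nchar(g$I) == nchar(product) - n, ,
            drop = FALSE]
  if (nrow(hits)) {
    prods <- vapply(seq_len(nrow(hits)), function(i) {
      rs <- t - v + hits$R[i] + hits$M[i] + 1L
      paste0(substr(locus$top_strand, 1L, t - hits$L[i]), hits$I[i],
             if (rs <= n) substr(locus$top_strand, rs, n) else "")
    }, character(1))
    hits <- hits[prods == product, , drop = FALSE]
  }
  if (!nrow(hits))
    stop(structure(class = c("nhejseq_unexplainable", "error", "condition"),
                   list(message = "product is not explainable within the configured limits",
                        call = sys.call())))
  hits <- hits[canonical_order(hits)[1], ]
  joint_descriptor(hits$L, hits$R, hits$M, hits$I, v)
}

# ---- identifiers -----------------------------------------------------------

#' Encode / decode joint identifiers
#'
#' The identifier renders the descriptor fields as
#' `"D{+n|-n|0}_M{m}_L{l}_R{r}"`, with `"_I{seq}"` appended when inserted
#' bases are present (insertions in lower case, matching the convention that
#' lower case marks non-templated bases). The precise religation joint
#' encodes as `"precise"`. `decode_joint_id()` inverts the encoding;
#' decoding `"precise"` needs the locus overhang length to reconstruct
#' `M = v`.
#'
#' @param desc A [joint_descriptor].
#' @return `encode_joint_id`: character scalar.
#' @examples
#' encode_joint_id(joint_descriptor(3, 0, 4, "", 4))  # "D-3_M4_L3_R0"
#' @export
encode_joint_id <- function(desc) {
  stopifnot(inherits(desc, "joint_descriptor"))
  if (desc$is_precise) return("precise")
  d <- if (desc$D > 0) sprintf("D+%d", desc$D) else sprintf("D%d", desc$D)
  id <- sprintf("%s_M%d_L%d_R%d", d, desc$M, desc$L, desc$R)
  if (nchar(desc$I) > 0L) id <- paste0(id, "_I", tolower(desc$I))
  id
}

#' @rdname encode_joint_id
#' @param id Character scalar identifier.
#' @param overhang_len Overhang length, required to decode `"precise"`.
#' @return `decode_joint_id`: a [joint_descriptor].
#' @export
decode_joint_id <- function(id, overhang_len) {
  stopifnot(is.character(id), length(id) == 1L)
  if (id == "precise")
    return(joint_descriptor(0L, 0L, overhang_len, "", overhang_len))
  m <- regmatches(id, regexec(
    "^D([+-]?[0-9]+)_M([0-9]+)_L([0-9]+)_R([0-9]+)(_I([acgt]{1,2}))?$", id))[[1]]
  if (!length(m)) stop("malformed joint identifier: '", id, "'")
  desc <- joint_descriptor(L = as.integer(m[4]), R = as.integer(m[5]),
                           M = as.integer(m[3]),
                           I = toupper(m[7]), overhang_len = overhang_len)
  if (desc$D != as.integer(m[2]))
    stop("joint identifier '", id, "' is inconsistent with overhang length ",
         overhang_len)
  desc
}

#' Moore-Haber style alias of simple joints
#'
#' Classic short names for the two simplest imprecise joint classes:
#' `"+XY"` for pure fill-in duplications (partial overhang annealing at
#' `0 < M < v` with `L = R = 0` and no insertion, duplicating the unannealed
#' overhang bases) and `"-XYZ"` for pure deletions whose deleted top-strand
#' segment is unambiguous (cannot be slid along a flanking repeat). Returns
#' `NULL` for every other joint, including the precise joint and insertion
#' joints.
#'
#' @param desc A canonical [joint_descriptor].
#' @param locus A [dsb_locus].
#' @return Character scalar alias or `NULL`.
#' @export
alias_moore_haber <- function(desc, locus) {
  stopifnot(inherits(desc, "joint_descriptor"), inherits(locus, "dsb_locus"))
  t <- locus$cut_pos; v <- locus$overhang_len; s <- locus$top_strand
  if (desc$is_precise || nchar(desc$I) > 0L) return(NULL)
  if (desc$L == 0L && desc$R == 0L && desc$M > 0L && desc$M < v) {
    dup <- substr(s, t - v + desc$M + 1L, t)
    return(paste0("+", dup))
  }
  if (desc$D < 0L) {
    a <- t - desc$L + 1L                       # first deleted base
    b <- t - v + desc$R + desc$M               # last deleted base
    if (a > b) return(NULL)
    # ambiguous if the deleted window can slide along a repeat
    left_slide <- a > 1L && substr(s, a - 1L, a - 1L) == substr(s, b, b)
    right_slide <- b < locus$n && substr(s, b + 1L, b + 1L) == substr(s, a, a)
    if (left_slide || right_slide) return(NULL)
    return(paste0("-", substr(s, a, b)))
  }
  NULL
}

#' Export a joint space as TSV / FASTA
#'
#' @param joints A `joint_space` data.frame from [enumerate_joints()].
#' @param tsv_path Path for a TSV of the descriptor table (optional).
#' @param fasta_path Path for a FASTA of read templates (optional).
#' @return Invisibly, `joints`.
#' @export
write_joint_space <- function(joints, tsv_path = NULL, fasta_path = NULL) {
  stopifnot(inherits(joints, "joint_space"))
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(joints), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    if (is.null(joints$read_template))
      stop("joint space has no read templates; enumerate with a layout")
    writeLines(paste0(">", joints$joint_id, "\n", joints$read_template),
               fasta_path)
  }
  invisible(joints)
}
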