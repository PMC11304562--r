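# Bridge to the RDKit batch backend (inst/python/chem_backend.py).
#
# All chemistry (canonicalization, Morgan fingerprints, SMARTS matching,
# SMIRKS application) is delegated to RDKit through short-lived batch
# subprocesses.  Results are memoised in a package-level cache so repeated
# work (the common case in pathway expansion and resampling experiments)
# never re-enters Python.

.chem_cache <- new.env(parent = emptyenv())

chem_cache_reset <- function() {
  rm(list = ls(.chem_cache, all.names = TRUE), envir = .chem_cache)
  invisible(NULL)
}

chem_python <- function() {
  opt <- getOption("rulepath.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("RULEPATH_PYTHON", "")
  if (nzchar(env)) return(env)
  "python"
}

chem_backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "rulepath")
  if (!nzchar(path)) {
    rlang::abort("chem_backend.py not found; is rulepath installed correctly?")
  }
  path
}

# ---- persistent backend server --------------------------------------------
# Amortizes interpreter startup over many small batches (pathway expansion
# issues hundreds of them). Falls back transparently to one-shot
# subprocesses when a socket server cannot be run.

chem_server_available <- function() {
  if (isTRUE(getOption("rulepath.no_server"))) return(FALSE)
  con <- .chem_cache[["__server_con__"]]
  !is.null(con) && inherits(con, "connection") && isOpen(con)
}

chem_server_stop <- function() {
  con <- .chem_cache[["__server_con__"]]
  if (!is.null(con)) {
    try(close(con), silent = TRUE)
    rm("__server_con__", envir = .chem_cache)
  }
  invisible(NULL)
}

chem_server_start <- function() {
  if (isTRUE(.chem_cache[["__server_failed__"]])) return(FALSE)
  port <- 20000L + (Sys.getpid() * 7L) %% 20000L
  for (attempt in 1:3) {
    suppressWarnings(system2(
      chem_python(),
      c(chem_backend_script(), "--serve", port + attempt - 1L),
      stdout = FALSE, stderr = FALSE, wait = FALSE
    ))
    for (i in 1:100) {
      con <- suppressWarnings(try(
        socketConnection("127.0.0.1", port + attempt - 1L, blocking = TRUE,
                         open = "r+b", timeout = 600),
        silent = TRUE
      ))
      if (!inherits(con, "try-error")) {
        .chem_cache[["__server_con__"]] <- con
        return(TRUE)
      }
      Sys.sleep(0.1)
    }
  }
  .chem_cache[["__server_failed__"]] <- TRUE
  FALSE
}

chem_server_call <- function(req) {
  if (isTRUE(getOption("rulepath.no_server"))) return(NULL)
  if (!chem_server_available() && !chem_server_start()) return(NULL)
  con <- .chem_cache[["__server_con__"]]
  payload <- jsonlite::toJSON(req, auto_unbox = TRUE, null = "null")
  ok <- try({
    writeLines(payload, con)
    flush(con)
    line <- readLines(con, n = 1)
    stopifnot(length(line) == 1, nzchar(line))
    jsonlite::parse_json(line)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    chem_server_stop()
    .chem_cache[["__server_failed__"]] <- TRUE
    return(NULL)
  }
  if (!is.null(ok$fatal)) {
    rlang::abort(paste0("chemistry backend error: ", ok$fatal))
  }
  ok
}

# Run one batch request against the backend. `req` is a list mirroring the
# JSON protocol documented at the top of chem_backend.py.
chem_backend_call <- function(req) {
  res <- chem_server_call(req)
  if (!is.null(res)) return(res)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  errfile <- tempfile(fileext = ".log")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, null = "null")
  status <- suppressWarnings(system2(
    chem_python(),
    c(chem_backend_script(), infile, outfile),
    stdout = FALSE, stderr = errfile
  ))
  if (!identical(status, 0L) || !file.exists(outfile)) {
    err <- if (file.exists(errfile)) readLines(errfile, warn = FALSE) else character(0)
    rlang::abort(c(
      "chemistry backend failed",
      i = paste0("python executable: ", chem_python()),
      i = paste0("exit status ", status),
      i = paste(utils::tail(err, 5), collapse = "\n")
    ))
  }
  jsonlite::read_json(outfile)
}

cache_key <- function(kind, ...) paste(kind, ..., sep = "\r")

cache_get <- function(keys) {
  mget(keys, envir = .chem_cache, ifnotfound = list(NULL))
}

cache_has <- function(keys) {
  vapply(keys, exists, logical(1), envir = .chem_cache, USE.NAMES = FALSE)
}

cache_set <- function(key, value) assign(key, value, envir = .chem_cache)

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the stereo-stripped canonical form used as compound
#' identity throughout rulepath.  Transformation rules carry no
#' stereochemistry, so pathway matching must not fail on unreported
#' stereocentres; stereo descriptors are removed before canonicalization.
#' The operation is idempotent: canonicalizing a canonical SMILES returns
#' it unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))          # identical keys
#' canonicalize_smiles("C[C@@H](N)C(=O)O")       # stereo stripped
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  if (any(is.na(smiles) | !nzchar(smiles))) {
    rlang::abort("SMILES must be non-empty strings", class = "rulepath_parse_error")
  }
  keys <- cache_key("canon", smiles)
  miss <- !cache_has(keys)
  if (any(miss)) {
    todo <- unique(smiles[miss])
    res <- chem_backend_call(list(canon = as.list(todo)))$canon
    for (item in res) {
      if (!is.null(item$error)) {
        rlang::abort(
          paste0("cannot parse SMILES: '", item$`in`, "'"),
          class = "rulepath_parse_error"
        )
      }
      cache_set(cache_key("canon", item$`in`), item$out)
      # canonical form maps to itself: saves a round-trip on idempotent use
      cache_set(cache_key("canon", item$out), item$out)
    }
  }
  unlist(cache_get(keys), use.names = FALSE)
}

# Morgan radius-2 fingerprints as sorted integer on-bit positions.
# Input SMILES are canonicalized first; returns a list named by the
# *input* smiles.
chem_fingerprints <- function(smiles, nbits = 2048L) {
  if (length(smiles) == 0) return(list())
  can <- canonicalize_smiles(smiles)
  keys <- cache_key("fp", nbits, can)
  miss <- !cache_has(keys)
  if (any(miss)) {
    todo <- unique(can[miss])
    res <- chem_backend_call(list(fp = as.list(todo), fp_nbits = nbits))$fp
    for (smi in names(res)) {
      cache_set(cache_key("fp", nbits, smi),
                as.integer(unlist(res[[smi]], use.names = FALSE)))
    }
  }
  out <- cache_get(keys)
  names(out) <- smiles
  out
}

# Apply each SMIRKS to each compound. Returns a list indexed
# [[smirks]][[canonical smiles]] -> list of character vectors (product
# sets, each sorted; the list deduplicated and sorted). Sanitization
# failures inside the backend drop the offending product set with a
# warning.
chem_apply <- function(smirks, smiles) {
  if (length(smiles) == 0 || length(smirks) == 0) {
    out <- rep(list(stats::setNames(list(), character(0))), length(smirks))
    names(out) <- smirks
    return(out)
  }
  can <- unique(canonicalize_smiles(smiles))
  jobs <- list()
  for (smk in unique(smirks)) {
    keys <- cache_key("apply", smk, can)
    miss <- can[!cache_has(keys)]
    if (length(miss)) {
      jobs[[length(jobs) + 1L]] <- list(smirks = smk, smiles = as.list(miss))
    }
  }
  if (length(jobs)) {
    res <- chem_backend_call(list(apply = jobs))$apply
    for (job in res) {
      if (!is.null(job$error)) {
        rlang::abort(paste0("bad rule SMIRKS: ", job$error),
                     class = "rulepath_parse_error")
      }
      for (smi in names(job$results)) {
        sets <- lapply(job$results[[smi]], function(s)
          unlist(s, use.names = FALSE))
        cache_set(cache_key("apply", job$smirks, smi), sets)
      }
      if (length(job$dropped)) {
        rlang::warn(paste0(
          "dropped ", sum(unlist(job$dropped)),
          " product set(s) failing valence sanitization (rule ",
          substr(job$smirks, 1, 40), "...)"
        ))
      }
    }
  }
  out <- lapply(unique(smirks), function(smk) {
    sets <- cache_get(cache_key("apply", smk, can))
    names(sets) <- can
    sets
  })
  names(out) <- unique(smirks)
  out
}

# SMARTS substructure matches. patterns: named character vector.
# Returns list indexed [[input smiles]][[pattern id]] -> list of integer
# vectors of (0-based) atom indices.
chem_smarts_matches <- function(smiles, patterns) {
  if (length(smiles) == 0) return(list())
  stopifnot(!is.null(names(patterns)))
  can <- canonicalize_smiles(smiles)
  pat_sig <- paste(names(patterns), patterns, collapse = ";")
  keys <- cache_key("smarts", pat_sig, can)
  miss <- !cache_has(keys)
  if (any(miss)) {
    todo <- unique(can[miss])
    res <- chem_backend_call(list(smarts = list(
      patterns = as.list(patterns), smiles = as.list(todo)
    )))$smarts
    for (smi in names(res)) {
      hits <- lapply(res[[smi]], function(ms)
        lapply(ms, function(m) as.integer(unlist(m, use.names = FALSE))))
      cache_set(cache_key("smarts", pat_sig, smi), hits)
    }
  }
  out <- cache_get(keys)
  names(out) <- smiles
  out
}
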