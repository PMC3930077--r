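## Minimal structured logger. Levels: debug < info < warn < error.
## Controlled by options(prognograde.log_level = "info"); output on stderr so
## document/table output on stdout stays clean for the CLI.

.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L, quiet = 5L)

.log <- function(level, msg) {
  min_level <- getOption("prognograde.log_level", "warn")
  if (.LOG_LEVELS[[level]] < .LOG_LEVELS[[min_level]]) return(invisible(NULL))
  cat(sprintf("[%s] %s %s\n", toupper(level),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg),
      file = stderr())
  invisible(NULL)
}

## digest of a file or an in-memory config, used in run logs
.digest_file <- function(path) unname(tools::md5sum(path))

.digest_config <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA), tmp)
  .digest_file(tmp)
}
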