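#!/usr/bin/env Rscript

# Thin command-line front-end over the bloomthin package.
# usage: bloomthin <subcommand> [--key value ...]   (see ?bloomthin_cli)

suppressPackageStartupMessages(library(bloomthin))
status <- bloomthin_cli(commandArgs(trailingOnly = TRUE))
quit(status = if (is.numeric(status)) status else 0L)
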