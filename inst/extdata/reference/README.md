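# Reference genome drop-in

Place the *Brevundimonas subvibrioides* ATCC 15264 reference chromosome
FASTA (uncompressed, `.fa`/`.fasta`/`.fna`) in this directory to enable the
genome-wide GANTC accounting: the corresponding acceptance check and
`scripts/acceptance.R` will then report the forward-strand GANTC occurrence
count of the chromosome. No sequence data is redistributed with the
package.
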