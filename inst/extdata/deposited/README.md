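# Deposited genome segments

The ten deposited paraxenovirus genome segments (five bisegmented genomes,
accessions LC876750–LC876759) are third-party archive data and are not
redistributed with this package. To run the deposited-genome annotation
check in the test suite and `check_deposited_orf_lengths()`, download the
segments from the public nucleotide archive into this directory as

    paraxenovirus_segments.fasta

with one FASTA record per segment; record ids should contain the genome
and segment labels (e.g. `GT4_RNA2`).
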