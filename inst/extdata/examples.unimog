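# Worked-example genomes used throughout the documentation.
# UniMoG dialect: '>' introduces a genome; chromosomes end in '|' (linear)
# or ')' (circular); '-' marks reverse orientation.
>degenerate_dup_A
1 3 2 -5 -4 3 5 4 |
>degenerate_dup_B
1 6 2 3 1 7 3 4 1 3 |
>two_chrom_A
1 -6 5 3 |
4 2 |
>two_chrom_B
1 7 2 3 4 5 |
7 -8 |
>canonical_A
2 1 |
4 3 |
>canonical_B
1 2 |
3 4 |
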