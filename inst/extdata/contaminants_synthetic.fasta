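>synthetic_albumin_like_1 synthetic stand-in for serum albumin carry-over (not a real sequence)
MKWVTFLLLLFISGSAFSRGVFRREAHKSEIAHRFKDLGEEHFKGLVLIAFSQYLQQCPF
DEHVKLVNELTEFAKTCVADESHAGCEKSLHTLFGDELCKVASLRETYGDMADCCEKQEP
ERNECFLSHKDDSPDLPKLKPDPNTLCDEFKADEKKFWGKYLYEIARRHPYFYAPELLYY
ANKYNGVFQECCQAEDKGACLLPKIETMREKVLASSARQRLRCASIQKFGERALKAWSVA
>synthetic_collagen_like_1 synthetic Gly-X-Y repeat collagen-like decoy
GPPGAPGPQGFQGPPGEPGEPGASGPMGPRGPPGPPGKNGDDGEAGKPGRPGERGPPGPQ
GARGLPGTAGLPGMKGHRGFSGLDGAKGDAGPAGPKGEPGSPGENGAPGQMGPRGLPGER
GRPGAPGPAGARGNDGATGAAGPPGPTGPAGPPGFPGAVGAKGEAGPQGPRGSEGPQGVR
>synthetic_keratin_like_1 synthetic keratin-like decoy
MSRQFSSRSGYRSGGGFSSGSAGIINYQRRTTSSSTRRSGGGGGRFSSCGGGGGSFGAGG
GFGSRSLVNLGGSKSISISVARGGGRGSGFGGGYGGGGFGGGYGGGSFGGGSFGGGGFGG
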