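>FAM01_seed
TPEDCFVWPNHDCMCVRGNAILPGDDWMCDRWNTWQQRVNRQIGCATEDMIHKVHLNSCFCRWTWCFGGDDEIWMYSTKH
LSGQAMFCHSLIIAYTFFPQPLCSTTWRQQQVPRIKHARRLFRRICITTCNFFACNMLVTVDVLTHTMTVATARGS
>FAM02_seed
AYCPQSIEHHNWPPVSAQLHVMCLPRQAFSTLWRIDVPETCVWHLQIHYHLYDITKQPHIWEFKYICRNRFSDQVVLAFA
DMQKEKCWEMRNAPVLHIEYWKIHYPFNVIRTWYFTICMW
>FAM03_seed
SRDEAFVYKYQKIEYRQHLQCFIPAHITKALDNQCIVRDVHFFNWIAGVCQFDHGSKIFLRSFPTQYIMQALMIMPTPGD
QIVSKSYNENIIEYMIFLMNIYREVLLAQIHKMWPALGMFRQMNMSYSMMGMQQGCHILAPDEL
>FAM04_seed
NMVSGNHSLMEWECVWETNSGYWIPKNVSIRGAMELLMCRPCFCTWTWEMRKNVGVFAFWRCIKNWWWPAGYGVYRVYLP
WGIRDTKVYEHYLLKTRVETDMYATDRGNMRDHLIFAAFVLHYCRHNKR
>FAM05_seed
WTVGGYPQNAPDHALQVFHQKTLHWLYALTTGLWAQRFCAWDPEFINECQCWHNNHMEITRVTKQYISAIERDVGPFTCT
TSVQNFHKHFNDNEACDGKKKPHNNHEKMTPPVNMYRCHWADWCNIEFIIHEQVGCYVLTEIKDVNASCYTLAAW
>FAM06_seed
QSMAYWIFIRSHTRPGNRTNLCANFQSIGHNRQRSHCTKVDQRNWTWLGEVAYSGVWIIYMKGQEECAYLRWIQDKQTFA
LVYCNMYWVFRAFEPQKVLITIYIHGYESGSLIVWSGCWPRAIHATMQKYALSFYCG
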