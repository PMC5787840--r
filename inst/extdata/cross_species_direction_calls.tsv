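# Direction of the drought-induced expression change of the Arabidopsis and
# rice homologues of the 23 selected potato drought-responsive genes,
# relative to the potato gene's response, as published for this gene set.
# Symbols: ↗ same direction (up), ↘ same direction (down), – no significant
# change, nd no data / no homologue, ≠ opposite direction.
potato_gene	arabidopsis_symbol	rice_symbol
PGSC0003DMG400001621	↗	↗
PGSC0003DMG400012174	–	↗
PGSC0003DMG400014293	–	↗
PGSC0003DMG400015019	–	nd
PGSC0003DMG400024849	–	↗
PGSC0003DMG401015935	–	↗
PGSC0003DMG400000723	–	nd
PGSC0003DMG400002943	–	nd
PGSC0003DMG400020629	–	nd
PGSC0003DMG400001771	–	≠
PGSC0003DMG400003688	↗	↗
PGSC0003DMG400005731	↗	↗
PGSC0003DMG400005917	↗	nd
PGSC0003DMG400008497	–	↗
PGSC0003DMG400019233	↗	↗
PGSC0003DMG400024093	nd	↗
PGSC0003DMG400039484	–	↗
PGSC0003DMG400006913	–	↘
PGSC0003DMG400007427	↘	↘
PGSC0003DMG400008018	–	nd
PGSC0003DMG400014954	–	nd
PGSC0003DMG400022225	↘	↘
PGSC0003DMG400023602	≠	↘
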