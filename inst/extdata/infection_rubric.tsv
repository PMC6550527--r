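score	description
0	No spots of lysis or plaques
1	Spots of lysis at highest 1-2 titers but no plaques
2	Superinfecting phage produces plaques with an efficiency of plating of less than ~1e-3-1e-4 or spots of lysis at highest 3 titers but no plaques
3	Superinfecting phage produces plaques with an efficiency of plating from 1e-1-1e-3 or spots of lysis at highest 4-5 titers but no plaques
4	Superinfecting phage produces plaques with an efficiency of plating of 1, but spots/plaques exhibit increased turbidity or reduced size compared to infection of the control host
5	Superinfecting phage produces plaques with an efficiency of plating of 1, and there is no phenotypic difference compared to infection of the control host
6	Superinfecting phage produces plaques with an efficiency of plating of 1, but spots/plaques exhibit reduced turbidity or increased size compared to infection of the control host
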