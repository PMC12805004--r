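# Kin-type inventories for the non-sibling kinship subdomains.
# These are PACKAGE-DEFAULT RECONSTRUCTIONS, shipped as editable
# configuration: the sibling inventory is fixed in code, but the five
# inventories below are plausible core-type sets (parallel in design to the
# sibling set) and may be replaced by passing `inventory_file=` to
# subdomain_kin_types(). Codes follow the grammar of parse_kin_type().
subdomain,code
parents_siblings,FB
parents_siblings,FZ
parents_siblings,MB
parents_siblings,MZ
parents_siblings,FeB
parents_siblings,FyB
parents_siblings,FeZ
parents_siblings,FyZ
parents_siblings,MeB
parents_siblings,MyB
parents_siblings,MeZ
parents_siblings,MyZ
grandparents,FF
grandparents,FM
grandparents,MF
grandparents,MM
grandchildren,SS
grandchildren,SD
grandchildren,DS
grandchildren,DD
nieces_nephews,mBS
nieces_nephews,mBD
nieces_nephews,mZS
nieces_nephews,mZD
nieces_nephews,fBS
nieces_nephews,fBD
nieces_nephews,fZS
nieces_nephews,fZD
cousins,FBS
cousins,FBD
cousins,FZS
cousins,FZD
cousins,MBS
cousins,MBD
cousins,MZS
cousins,MZD
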