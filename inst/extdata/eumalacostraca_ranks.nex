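#NEXUS
BEGIN DATA;
  DIMENSIONS NTAX=7 NCHAR=33;
  FORMAT DATATYPE=STANDARD SYMBOLS="123456789abc" MISSING=z;
  MATRIX
    Af           22776zz122222277798z777zz2777z354
    Gf           113447545a74548a7a55aa4742556922a
    Si           11777ba7334243998998998a83889a556
    Nh           113337424924225555545545424446328
    Pf           112226429992227237537735323346z28
    Ni           133335359977566766747746z45568zz2
    Ph           11222546bb888989z88z8869z33337zza
  ;
END;
BEGIN TREES;
  TREE tree1 = [&R] (Af,(Gf,((Si,(Nh,Pf)Pleocyemata_LCA)Decapoda_LCA,(Ni,Ph)Peracarida_LCA)Caridoida_LCA)Eumalacostraca_LCA)Branchiopod_Malacostracan_LCA;
END;
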