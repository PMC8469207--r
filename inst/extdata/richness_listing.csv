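component,subgroup,higher_group,n_taxa
plankton,phytoplankton,Chlorophyta,18
plankton,phytoplankton,Bacillariophyta,16
plankton,phytoplankton,Cyanophyta,8
plankton,phytoplankton,Ochrophyta,7
plankton,phytoplankton,Miozoa,4
plankton,phytoplankton,Cryptophyta,2
plankton,phytoplankton,Charophyta,1
plankton,zooplankton,Rotifera,20
plankton,zooplankton,Cladocera,10
plankton,zooplankton,Copepoda,6
benthic_flora,macroalgae,Chlorophyta,17
benthic_flora,macroalgae,Cyanophyta,8
benthic_flora,macroalgae,Charophyta,4
benthic_flora,macroalgae,Ochrophyta,1
benthic_flora,microalgae,Bacillariophyta,52
benthic_flora,macrophytes,Tracheophyta,6
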