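# Pennsylvania 67-county adjacency (shared land borders), undirected edge list.
# Reconstructed from public county maps; counties that meet only near a
# corner point may be coded differently in other renderings of this graph.
# One edge per line: "countyA countyB".
Erie Crawford
Erie Warren
Crawford Warren
Crawford Venango
Crawford Mercer
Warren Venango
Warren Forest
Warren McKean
Mercer Venango
Mercer Lawrence
Mercer Butler
Venango Forest
Venango Clarion
Venango Butler
Forest Clarion
Forest Jefferson
Forest Elk
McKean Potter
McKean Cameron
McKean Elk
Elk Cameron
Elk Jefferson
Elk Clearfield
Cameron Potter
Cameron Clinton
Cameron Clearfield
Potter Tioga
Potter Clinton
Lawrence Butler
Lawrence Beaver
Butler Beaver
Butler Allegheny
Butler Armstrong
Butler Clarion
Clarion Jefferson
Clarion Armstrong
Jefferson Clearfield
Jefferson Indiana
Jefferson Armstrong
Beaver Allegheny
Beaver Washington
Allegheny Washington
Allegheny Westmoreland
Allegheny Armstrong
Armstrong Indiana
Armstrong Westmoreland
Washington Greene
Washington Fayette
Washington Westmoreland
Greene Fayette
Fayette Westmoreland
Fayette Somerset
Westmoreland Indiana
Westmoreland Somerset
Westmoreland Cambria
Indiana Cambria
Indiana Clearfield
Cambria Somerset
Cambria Bedford
Cambria Blair
Cambria Clearfield
Somerset Bedford
Bedford Blair
Bedford Fulton
Bedford Huntingdon
Blair Clearfield
Blair Centre
Blair Huntingdon
Clearfield Centre
Clearfield Clinton
Centre Clinton
Centre Union
Centre Mifflin
Centre Huntingdon
Clinton Lycoming
Clinton Union
Lycoming Tioga
Lycoming Bradford
Lycoming Sullivan
Lycoming Union
Lycoming Northumberland
Lycoming Montour
Lycoming Columbia
Tioga Bradford
Bradford Susquehanna
Bradford Wyoming
Bradford Sullivan
Sullivan Wyoming
Sullivan Luzerne
Sullivan Columbia
Susquehanna Wayne
Susquehanna Wyoming
Susquehanna Lackawanna
Wayne Pike
Wayne Lackawanna
Lackawanna Wyoming
Lackawanna Luzerne
Lackawanna Monroe
Wyoming Luzerne
Luzerne Columbia
Luzerne Schuylkill
Luzerne Carbon
Luzerne Monroe
Pike Monroe
Monroe Carbon
Monroe Northampton
Columbia Montour
Columbia Northumberland
Columbia Schuylkill
Montour Northumberland
Northumberland Union
Northumberland Snyder
Northumberland Dauphin
Northumberland Schuylkill
Union Snyder
Snyder Mifflin
Snyder Juniata
Mifflin Juniata
Mifflin Huntingdon
Juniata Perry
Juniata Huntingdon
Huntingdon Fulton
Huntingdon Franklin
Fulton Franklin
Franklin Cumberland
Franklin Adams
Franklin Perry
Perry Cumberland
Perry Dauphin
Cumberland Adams
Cumberland York
Cumberland Dauphin
Adams York
York Lancaster
York Dauphin
Dauphin Lebanon
Dauphin Lancaster
Dauphin Schuylkill
Lebanon Lancaster
Lebanon Berks
Lebanon Schuylkill
Lancaster Chester
Lancaster Berks
Schuylkill Berks
Schuylkill Lehigh
Schuylkill Carbon
Carbon Lehigh
Carbon Northampton
Berks Lehigh
Berks Montgomery
Berks Chester
Lehigh Northampton
Lehigh Bucks
Lehigh Montgomery
Northampton Bucks
Bucks Montgomery
Bucks Philadelphia
Montgomery Philadelphia
Montgomery Chester
Montgomery Delaware
Chester Delaware
Delaware Philadelphia
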